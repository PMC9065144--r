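## Genome-wide summaries: LD scores, LD-score-regression heritability with
## block-jackknife SEs, eigenvalue-weighted average heritability, the
## rescaled multivariate chi-squared, and LD-block signal overlap.

#' Per-SNP LD scores
#'
#' For each SNP, `l_j` is the sum of dosage r-squared with every SNP
#' within `window_bp` of its position on the same chromosome, including
#' itself (`r^2 = 1`), so `l_j >= 1`.
#'
#' @param G A `genotype_matrix` (QC-passed SNPs).
#' @param window_bp Window half-width in base pairs.
#' @return Data.frame per SNP: `snp`, `pos`, `block`, `ld_score`.
#' @export
compute_ld_scores <- function(G, window_bp = 1e6) {
  D <- G$dosages
  storage.mode(D) <- "double"
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  m <- ncol(D)
  R2 <- suppressWarnings(cor(D))^2
  R2[!is.finite(R2)] <- 0
  ell <- vapply(seq_len(m), function(j) {
    inwin <- G$chr == G$chr[j] & abs(G$pos - G$pos[j]) <= window_bp
    inwin[j] <- TRUE
    1 + sum(R2[j, inwin]) - R2[j, j]  # self counted exactly once as 1
  }, numeric(1))
  data.frame(snp = G$snp, pos = G$pos,
             block = G$block %||% rep(1L, m), ld_score = ell)
}

#' LD-score-regression heritability
#'
#' Fits the LD-score regression expectation `E[chi2_j] = 1 + n h2 l_j / M`
#' by (unweighted) least squares of the per-SNP chi-squared statistics on
#' the LD scores; the slope times `M / n` estimates h2. The standard
#' error comes from a delete-one block jackknife over LD blocks.
#'
#' @param chi2 Per-SNP chi-squared statistics (nonnegative).
#' @param ld LD-score table from [compute_ld_scores()] (or a data.frame
#'   with `ld_score` and `block`).
#' @param n GWAS sample size.
#' @param M Number of SNPs the heritability is spread over.
#' @param n_blocks Number of jackknife blocks used when `ld$block` has
#'   fewer than 2 distinct values (contiguous chunks; default 20).
#' @return List with `h2`, `se`, `slope`, `n_blocks`. The intercept is
#'   estimated freely rather than fixed at 1.
#' @export
ldsc_h2 <- function(chi2, ld, n, M, n_blocks = 20L) {
  stopifnot(length(chi2) == nrow(ld), all(chi2 >= 0, na.rm = TRUE),
            n > 0, M > 0)
  ell <- ld$ld_score
  if (var(ell) == 0) stop2("no variation in LD scores; slope unidentifiable")
  blocks <- ld$block
  if (length(unique(blocks)) < 2) {
    blocks <- as.integer(cut(seq_along(ell), breaks = n_blocks))
  }
  slope_of <- function(keep) {
    f <- lm(chi2[keep] ~ ell[keep])
    unname(f$coefficients[2])
  }
  all_idx <- seq_along(ell)
  slope <- slope_of(all_idx)
  ub <- unique(blocks)
  theta <- vapply(ub, function(b) slope_of(all_idx[blocks != b]), numeric(1))
  Bn <- length(ub)
  se_slope <- sqrt((Bn - 1) / Bn * sum((theta - mean(theta))^2))
  list(h2 = slope * M / n, se = se_slope * M / n, slope = slope,
       n_blocks = Bn)
}

#' Eigenvalue-weighted average heritability across PCs
#'
#' `sum_k lambda_k h2_k / sum_k lambda_k`: the average heritability of a
#' high-dimensional phenotype is the per-PC LD-score-regression estimate
#' weighted by the PC eigenvalues.
#'
#' @param h2_per_pc Per-PC heritability estimates.
#' @param lambda Matching eigenvalues (nonnegative, not all zero).
#' @return The weighted average.
#' @export
average_h2 <- function(h2_per_pc, lambda) {
  if (length(h2_per_pc) != length(lambda)) stop2("lengths differ")
  if (any(lambda < 0)) stop2("eigenvalues must be nonnegative")
  if (sum(lambda) <= 0) stop2("eigenvalues sum to zero")
  sum(lambda * h2_per_pc) / sum(lambda)
}

#' Rescale a multivariate chi-squared statistic to unit null mean
#'
#' Divides the K-df combined statistic by K so its null expectation is 1,
#' matching the unit-mean convention of a 1-df chi-squared expected by
#' (stratified) LD-score regression.
#'
#' @param T_stat Combined statistic(s).
#' @param K Degrees of freedom (number of PCs combined).
#' @return `T_stat / K`.
#' @export
scaled_chi2 <- function(T_stat, K) {
  if (any(K < 1)) stop2("K must be >= 1")
  T_stat / K
}

#' Per-block signal profile: mean -log10 p within each LD block
#'
#' @param ss Summary-statistics data.frame with `p` and a `block`
#'   assignment per SNP (column `block`, or supplied separately).
#' @param blocks Optional block id vector overriding `ss$block`.
#' @param cap Cap on `-log10 p` (default 320) guarding against underflow.
#' @return Data.frame per block: `block`, `mean_log10p`, `n_snps`. Empty
#'   blocks are dropped with a warning.
#' @export
block_profile <- function(ss, blocks = NULL, cap = 320) {
  b <- blocks %||% ss$block
  if (is.null(b)) stop2("no block assignment supplied")
  if (length(b) != nrow(ss)) stop2("block assignment length mismatch")
  lp <- pmin(-log10(pmax(ss$p, 1e-320)), cap)
  keep <- !is.na(lp)
  if (!all(keep)) warning("dropping ", sum(!keep), " SNPs with missing p")
  agg <- tapply(lp[keep], b[keep], mean)
  data.frame(block = names(agg), mean_log10p = as.vector(agg),
             n_snps = as.vector(tapply(lp[keep], b[keep], length)))
}

#' Genome-wide signal overlap between two traits
#'
#' Spearman rank correlation (ties mid-ranked, two-sided p via the t
#' approximation) between the per-LD-block mean `-log10 p` profiles of
#' two GWAS.
#'
#' @param a,b Block profiles from [block_profile()] on the same block
#'   universe (matched by block id).
#' @return List with `rho`, `p`, `n_blocks`.
#' @export
overlap_rho <- function(a, b) {
  idx <- match(a$block, b$block)
  if (anyNA(idx)) stop2("block universes differ")
  x <- a$mean_log10p
  y <- b$mean_log10p[idx]
  if (length(x) < 3) stop2("need at least 3 blocks")
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_blocks = length(x))
}
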