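## Discovery-stage multivariate GWAS: PCA of voxel phenotypes, per-PC
## covariate-adjusted association, combined-principal-component (CPC)
## statistics with a closed-form chi-squared null, and back-projection of
## per-PC effects to voxel space.

#' Principal-component basis of a voxel phenotype set
#'
#' Centers the subject x voxel matrix and extracts the leading `K`
#' principal components by singular value decomposition. Column signs are
#' fixed so the largest-magnitude loading of each eigenvector is positive,
#' making the basis reproducible.
#'
#' @param Y A `phenotype_volumes` object or a plain subject x voxel matrix.
#' @param K Number of components, `K <= min(subjects - 1, voxels)`.
#' @return A `pc_basis`: `vectors` (voxel x K, orthonormal), `values`
#'   (eigenvalues of the sample covariance, descending), `scores`
#'   (subject x K, centered), `center` (voxel means), `cum_var`
#'   (cumulative fraction of total variance), `grid_dims` if available.
#' @export
fit_pca <- function(Y, K) {
  vals <- if (inherits(Y, "phenotype_volumes")) Y$values else as.matrix(Y)
  n <- nrow(vals); V <- ncol(vals)
  if (K > min(n - 1, V)) stop2("K must be <= min(subjects - 1, voxels)")
  ctr <- colMeans(vals)
  Yc <- sweep(vals, 2, ctr)
  sv <- svd(Yc, nu = 0, nv = K)
  v <- sv$v
  for (k in seq_len(K)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) v[, k] <- -v[, k]
  }
  structure(list(
    vectors = v,
    values = sv$d[seq_len(K)]^2 / (n - 1),
    scores = Yc %*% v,
    center = ctr,
    cum_var = cumsum(sv$d^2)[seq_len(K)] / sum(sv$d^2),
    grid_dims = if (inherits(Y, "phenotype_volumes")) Y$grid_dims else NULL
  ), class = "pc_basis")
}

## covariate data.frame (or matrix) -> full-rank design with intercept
covariate_design <- function(Z, n = NULL) {
  if (is.null(Z)) {
    stopifnot(!is.null(n))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  M <- if (is.data.frame(Z)) model.matrix(~ ., data = Z) else {
    Zm <- as.matrix(Z)
    if (!any(apply(Zm, 2, function(c) all(c == c[1])))) {
      cbind(`(Intercept)` = 1, Zm)
    } else Zm
  }
  q <- qr(M)
  if (q$rank < ncol(M)) {
    bad <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    stop2("covariate design is rank deficient; collinear columns: ",
          paste(bad, collapse = ", "))
  }
  M
}

#' Residualize a matrix on covariates
#'
#' Returns `M - Z (Z'Z)^{-1} Z' M`, the least-squares residuals of every
#' column of `M` on the covariate design (intercept included).
#'
#' @param M Subject x p numeric matrix (or vector).
#' @param Z Covariate data.frame/matrix, or `NULL` for intercept only.
#' @return Matrix of residuals, orthogonal to every covariate column.
#' @export
residualize <- function(M, Z = NULL) {
  M <- as.matrix(M)
  D <- covariate_design(Z, n = nrow(M))
  qr.resid(qr(D), M)
}

#' Per-PC Wald statistics for every SNP
#'
#' Residualizes both the (per-SNP mean-imputed) dosages and the PC scores
#' on the covariates, then computes for each SNP x PC pair the marginal
#' regression coefficient, its standard error, and the Wald statistic
#' `W = beta / se`. By the Frisch-Waugh theorem these equal the full-design
#' multiple-regression t-statistics (score ~ dosage + covariates); the
#' statistic is invariant to the regression direction. SNPs with zero
#' residual dosage variance are flagged and their statistics set missing.
#'
#' @param basis A `pc_basis` from [fit_pca()].
#' @param G A `genotype_matrix` on the same subjects.
#' @param Z Covariate data.frame (or `NULL`).
#' @return A `per_pc_assoc`: `beta`, `se`, `W` (SNP x PC matrices), `df`
#'   (residual degrees of freedom), `snp`, `flagged` (logical per SNP).
#' @export
per_pc_wald <- function(basis, G, Z = NULL) {
  stopifnot(inherits(basis, "pc_basis"))
  S <- basis$scores
  n <- nrow(S)
  if (nrow(G$dosages) != n) stop2("subject counts differ")
  D <- G$dosages
  storage.mode(D) <- "double"
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  Zd <- covariate_design(Z, n = n)
  q <- qr(Zd)
  Sr <- qr.resid(q, S)
  Dr <- qr.resid(q, D)
  gss <- colSums(Dr^2)
  flagged <- gss < n * 1e-12
  gss_safe <- ifelse(flagged, NA_real_, gss)
  cross <- crossprod(Dr, Sr)                     # m x K
  beta <- cross / gss_safe
  df <- n - ncol(Zd) - 1L
  sss <- matrix(colSums(Sr^2), nrow(cross), ncol(cross), byrow = TRUE)
  sigma2 <- (sss - beta * cross) / df
  se <- sqrt(sigma2 / gss_safe)
  W <- beta / se
  structure(list(beta = beta, se = se, W = W, df = df,
                 snp = G$snp, flagged = flagged),
            class = "per_pc_assoc")
}

#' Combine per-PC Wald statistics as a chi-squared sum
#'
#' The CPC omnibus statistic: with orthogonal PCs the per-PC Wald
#' statistics are independent standard normal under the null, so the sum
#' of their squares follows a chi-squared distribution with as many
#' degrees of freedom as PCs combined. Missing entries are dropped with a
#' matching reduction in degrees of freedom.
#'
#' @param W Numeric vector of Wald statistics, or SNP x PC matrix.
#' @return Data.frame with `stat`, `df`, `p` (one row per SNP).
#' @export
combine_sum <- function(W) {
  W <- rbind(W)
  if (ncol(W) == 0) stop2("empty Wald statistic row")
  stat <- rowSums(W^2, na.rm = TRUE)
  df <- rowSums(!is.na(W))
  p <- ifelse(df > 0, pchisq(stat, df, lower.tail = FALSE), NA_real_)
  stat[df == 0] <- NA_real_
  data.frame(stat = stat, df = df, p = p)
}

#' Global-local combination of head and tail PC blocks (Fisher's method)
#'
#' Splits the PCs at cut point `C` into a head (the leading `C` PCs,
#' carrying global structure) and a tail, computes a chi-squared sum
#' p-value for each block, and combines the two p-values with Fisher's
#' method: `X = -2 (log p_head + log p_tail)`, referred to a chi-squared
#' distribution with 4 degrees of freedom. Computed in log space so deep
#' tails do not underflow.
#'
#' @param W Vector or SNP x PC matrix of Wald statistics.
#' @param C Cut point, `1 <= C < K`; if `C >= K` the full sum is returned
#'   with a warning.
#' @return Data.frame with `stat` (Fisher X), `p`.
#' @export
combine_global_local <- function(W, C) {
  W <- rbind(W)
  K <- ncol(W)
  if (C >= K) {
    warning("cut point >= number of PCs; falling back to the full sum")
    cs <- combine_sum(W)
    return(data.frame(stat = cs$stat, p = cs$p))
  }
  block_logp <- function(Wb) {
    df <- rowSums(!is.na(Wb))
    ifelse(df > 0,
           pchisq(rowSums(Wb^2, na.rm = TRUE), df,
                  lower.tail = FALSE, log.p = TRUE),
           NA_real_)
  }
  lp_head <- block_logp(W[, seq_len(C), drop = FALSE])
  lp_tail <- block_logp(W[, (C + 1):K, drop = FALSE])
  X <- -2 * (lp_head + lp_tail)
  data.frame(stat = X, p = pchisq(X, df = 4, lower.tail = FALSE))
}

#' Default genome-wide significance threshold
#'
#' `5e-8` corrected for the number of combination rules searched and the
#' number of phenotype features analyzed (e.g. 4 global-local cut points x
#' 3 tissue features gives `5e-8 / 12 = 4.2e-9`, rounded as reported).
#'
#' @param n_rules Number of combination rules (cut points) searched.
#' @param n_features Number of phenotype features analyzed.
#' @return The Bonferroni-adjusted threshold `5e-8 / (n_rules * n_features)`.
#' @export
cpc_alpha <- function(n_rules = 4, n_features = 3) {
  5e-8 / (n_rules * n_features)
}

#' Apply all CPC combination rules per SNP
#'
#' Computes the full chi-squared sum and the global-local Fisher
#' combination at every cut point for each SNP, takes the best (smallest
#' p) rule, and flags genome-wide significance.
#'
#' @param assoc A `per_pc_assoc` from [per_pc_wald()].
#' @param cut_points Integer vector of global-local cut points (each `< K`).
#' @param alpha Significance threshold; `NULL` uses
#'   [cpc_alpha()]`(length(cut_points), n_features)`.
#' @param n_features Feature multiplicity entering the default threshold.
#' @return A `cpc_result` data.frame: per SNP the sum-rule statistic/p,
#'   one p per cut point, `best_rule`, `best_p`, `significant`.
#' @export
run_cpc <- function(assoc, cut_points = c(5, 10, 25), alpha = NULL,
                    n_features = 3) {
  stopifnot(inherits(assoc, "per_pc_assoc"))
  K <- ncol(assoc$W)
  if (any(cut_points < 1 | cut_points >= K))
    stop2("cut points must satisfy 1 <= C < K")
  if (is.null(alpha)) alpha <- cpc_alpha(length(cut_points), n_features)
  cs <- combine_sum(assoc$W)
  res <- data.frame(snp = assoc$snp, stat_sum = cs$stat, df_sum = cs$df,
                    p_sum = cs$p)
  pmat <- matrix(cs$p, nrow(res), 1 + length(cut_points))
  rules <- c("sum", paste0("gl", cut_points))
  for (i in seq_along(cut_points)) {
    gl <- combine_global_local(assoc$W, cut_points[i])
    res[[paste0("p_gl", cut_points[i])]] <- gl$p
    pmat[, i + 1] <- gl$p
  }
  best <- apply(pmat, 1, function(p)
    if (all(is.na(p))) NA_integer_ else which.min(p))
  res$best_rule <- rules[best]
  res$best_p <- pmat[cbind(seq_len(nrow(pmat)), best)]
  res$significant <- !is.na(res$best_p) & res$best_p < alpha
  attr(res, "alpha") <- alpha
  attr(res, "cut_points") <- cut_points
  class(res) <- c("cpc_result", "data.frame")
  res
}

#' Back-project per-PC coefficients to voxel space
#'
#' Linear change of basis: the voxelwise effect map implied by per-PC
#' regression coefficients is `beta_hat_i = sum_{k<=K_use} beta_k v_ki`.
#'
#' @param basis A `pc_basis`.
#' @param beta_row Numeric vector of per-PC coefficients (length `>= K_use`).
#' @param K_use Number of leading components to use (default: all).
#' @return Numeric voxel vector (a voxel beta map).
#' @export
backproject <- function(basis, beta_row, K_use = ncol(basis$vectors)) {
  stopifnot(inherits(basis, "pc_basis"), K_use <= ncol(basis$vectors))
  b <- beta_row[seq_len(K_use)]
  b[is.na(b)] <- 0
  drop(basis$vectors[, seq_len(K_use), drop = FALSE] %*% b)
}

#' Combined-principal-component multivariate GWAS
#'
#' The discovery-stage model fit: extracts `K` principal components from
#' the voxelwise phenotypes, computes covariate-adjusted per-PC Wald
#' statistics for every SNP, combines them with the chi-squared sum rule
#' and global-local Fisher rules at each cut point, and assembles a
#' summary-statistics table.
#'
#' @param phenotypes A `phenotype_volumes` object (or subject x voxel
#'   matrix).
#' @param genotypes A `genotype_matrix` on the same subjects (QC-passed).
#' @param covariates Covariate data.frame (or `NULL`).
#' @param K Number of principal components (default 50, truncated to what
#'   the data support is an error, not silent).
#' @param cut_points Global-local cut points, each `< K`.
#' @param alpha Significance threshold (`NULL`: [cpc_alpha()] default with
#'   `n_features`).
#' @param n_features Multiplicity of features in the wider analysis, used
#'   only for the default threshold.
#' @param feature Label recorded in the summary statistics.
#' @return An object of class `cpc_gwas` with components `basis`
#'   (`pc_basis`), `assoc` (`per_pc_assoc`), `result` (`cpc_result`),
#'   `summary_stats` (per-SNP table with `snp`, `chr`, `pos`, `stat`, `p`,
#'   `feature`, `rule`), `alpha`, `K`, `cut_points`, `feature`.
#' @seealso [clump_loci()], [polyvoxel_score()], [enrichment_profile()]
#' @export
cpc_gwas <- function(phenotypes, genotypes, covariates = NULL, K = 50,
                     cut_points = c(5, 10, 25), alpha = NULL,
                     n_features = 3, feature = "pheno") {
  basis <- fit_pca(phenotypes, K)
  assoc <- per_pc_wald(basis, genotypes, covariates)
  result <- run_cpc(assoc, cut_points = cut_points, alpha = alpha,
                    n_features = n_features)
  ss <- data.frame(snp = genotypes$snp, chr = genotypes$chr,
                   pos = genotypes$pos, stat = result$stat_sum,
                   p = result$best_p, feature = feature,
                   rule = result$best_rule)
  structure(list(basis = basis, assoc = assoc, result = result,
                 summary_stats = ss, alpha = attr(result, "alpha"),
                 K = K, cut_points = cut_points, feature = feature,
                 n_subjects = nrow(genotypes$dosages)),
            class = "cpc_gwas")
}

#' @export
print.cpc_gwas <- function(x, ...) {
  cat("Combined-principal-component multivariate GWAS\n")
  cat(sprintf("  feature: %s | subjects: %d | SNPs: %d | PCs: %d (%.1f%% variance)\n",
              x$feature, x$n_subjects, nrow(x$result), x$K,
              100 * x$basis$cum_var[x$K]))
  cat(sprintf("  rules: sum + global-local cuts {%s} | alpha = %.3g\n",
              paste(x$cut_points, collapse = ", "), x$alpha))
  cat(sprintf("  significant SNPs: %d\n", sum(x$result$significant)))
  invisible(x)
}

#' @export
summary.cpc_gwas <- function(object, n_top = 5, ...) {
  print(object)
  sig <- object$result[object$result$significant, , drop = FALSE]
  top <- object$result[order(object$result$best_p), , drop = FALSE]
  cat("\nTop SNPs by combined p-value:\n")
  print(head(top[, c("snp", "stat_sum", "p_sum", "best_rule", "best_p",
                     "significant")], n_top), row.names = FALSE)
  invisible(list(significant = sig, top = head(top, n_top)))
}

#' @export
coef.cpc_gwas <- function(object, ...) object$assoc$beta

#' Manhattan-style plot of combined p-values
#'
#' @param x A `cpc_gwas` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cpc_gwas <- function(x, ...) {
  ss <- x$summary_stats
  lp <- -log10(pmax(ss$p, 1e-320))
  plot(ss$pos / 1e6, lp, pch = 16, cex = 0.5,
       xlab = "position (Mb)", ylab = expression(-log[10](p)),
       main = sprintf("CPC GWAS: %s", x$feature), ...)
  abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}
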