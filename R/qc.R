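## Variant QC, pairwise LD, significance clumping into loci, and merging
## of loci across features.

#' Variant quality-control filters
#'
#' Flags SNPs by minor allele frequency, Hardy-Weinberg disequilibrium
#' (1-df chi-squared on observed vs expected genotype counts among
#' non-missing subjects, no continuity correction), and missingness. A SNP
#' is kept iff `MAF >= maf_min` and `HWE p >= hwe_p_min` and
#' `missing fraction <= miss_max` (the missingness filter removes strictly
#' greater-than, so a fraction exactly at the threshold is retained).
#'
#' @param G A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.005).
#' @param hwe_p_min Minimum Hardy-Weinberg p-value (default 1e-10).
#' @param miss_max Maximum missing fraction (default 0.05).
#' @return Data.frame with per-SNP `snp`, `af`, `maf`, `hwe_p`,
#'   `missing`, `kept`, `reason` (`NA` if kept; first failed filter among
#'   missingness, maf, hwe otherwise).
#' @export
variant_filters <- function(G, maf_min = 0.005, hwe_p_min = 1e-10,
                            miss_max = 0.05) {
  D <- G$dosages
  n <- nrow(D)
  miss <- colMeans(is.na(D))
  af <- colMeans(D, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(D)), function(j) {
    d <- D[, j]; d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
    p <- (obs[2] + 2 * obs[3]) / (2 * length(d))
    expd <- length(d) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    if (any(expd == 0)) return(1)  # monomorphic: fits trivially
    chi2 <- sum((obs - expd)^2 / expd)
    pchisq(chi2, df = 1, lower.tail = FALSE)
  }, numeric(1))
  pass_miss <- miss <= miss_max
  pass_maf <- !is.na(maf) & maf >= maf_min
  pass_hwe <- !is.na(hwe_p) & hwe_p >= hwe_p_min
  kept <- pass_miss & pass_maf & pass_hwe
  reason <- rep(NA_character_, ncol(D))
  reason[!pass_hwe] <- "hwe"
  reason[!pass_maf] <- "maf"
  reason[!pass_miss] <- "missingness"
  data.frame(snp = G$snp, af = af, maf = maf, hwe_p = hwe_p,
             missing = miss, kept = kept, reason = reason)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of dosages over pairwise-complete subjects
#' (composite LD; phase is unavailable from dosage data).
#'
#' @param G A `genotype_matrix`.
#' @param i,j SNP column indices.
#' @return r-squared in `[0, 1]`, or `NA` if either SNP has zero dosage
#'   variance among pairwise-complete subjects.
#' @export
ld_r2 <- function(G, i, j) {
  x <- G$dosages[, i]; y <- G$dosages[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

## r^2 of one SNP against a set, pairwise complete
ld_r2_vec <- function(D, lead, idx) {
  r <- suppressWarnings(
    cor(D[, lead], D[, idx, drop = FALSE], use = "pairwise.complete.obs"))
  as.vector(r)^2
}

#' Clump significant SNPs into loci around lead SNPs
#'
#' Greedy locus definition: repeatedly take the unassigned significant SNP
#' with the smallest p-value as a lead (ties broken by position, then SNP
#' id), and absorb every unassigned significant SNP on the same chromosome
#' that is either in LD with the lead (`r^2 > r2_thresh`) or within
#' `window_bp` of the lead position. The locus span is the min/max of
#' member positions.
#'
#' @param ss Summary-statistics data.frame with columns `snp`, `chr`,
#'   `pos`, `p` (and optionally `stat`, `feature`, `rule`).
#' @param G The `genotype_matrix` sharing `ss`'s SNP universe (matched by
#'   SNP id), used for LD.
#' @param p_thresh Genome-wide significance threshold (default `4.2e-9`,
#'   i.e. 5e-8 corrected for 4 combination rules x 3 features).
#' @param r2_thresh LD threshold (default 0.1).
#' @param window_bp Lead-to-member distance window in bp (default 250000).
#' @return A locus table data.frame: `locus`, `lead_snp`, `chr`, `start`,
#'   `end`, `n_snps`, `min_p`, `members` (comma-separated SNP ids),
#'   `features` (comma-separated provenance). Empty if nothing is
#'   significant.
#' @export
clump_loci <- function(ss, G, p_thresh = 4.2e-9, r2_thresh = 0.1,
                       window_bp = 250000) {
  sig <- ss[!is.na(ss$p) & ss$p < p_thresh, , drop = FALSE]
  empty <- data.frame(locus = integer(0), lead_snp = character(0),
                      chr = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      min_p = numeric(0), members = character(0),
                      features = character(0))
  if (nrow(sig) == 0) return(empty)
  sig <- sig[order(sig$p, sig$pos, sig$snp), , drop = FALSE]
  col <- match(sig$snp, G$snp)
  if (anyNA(col)) stop2("summary stats contain SNPs absent from genotypes")
  assigned <- rep(FALSE, nrow(sig))
  out <- list()
  while (any(!assigned)) {
    lead <- which(!assigned)[1]
    cand <- which(!assigned & sig$chr == sig$chr[lead])
    r2 <- ld_r2_vec(G$dosages, col[lead], col[cand])
    near <- abs(sig$pos[cand] - sig$pos[lead]) <= window_bp
    take <- cand[(!is.na(r2) & r2 > r2_thresh) | near]
    take <- union(lead, take)
    assigned[take] <- TRUE
    feats <- if ("feature" %in% names(sig)) {
      paste(sort(unique(sig$feature[take])), collapse = ",")
    } else ""
    out[[length(out) + 1]] <- data.frame(
      lead_snp = sig$snp[lead], chr = sig$chr[lead],
      start = min(sig$pos[take]), end = max(sig$pos[take]),
      n_snps = length(take), min_p = min(sig$p[take]),
      members = paste(sig$snp[sort(take)], collapse = ","),
      features = feats)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chr, res$start), , drop = FALSE]
  rownames(res) <- NULL
  cbind(locus = seq_len(nrow(res)), res)
}

#' Merge loci with overlapping genomic ranges across feature tables
#'
#' Unions loci whose `[start, end]` ranges overlap on the same chromosome,
#' accumulating feature provenance; the merged lead is the member lead with
#' the smallest p-value.
#'
#' @param tables List of locus tables as returned by [clump_loci()].
#' @return One merged locus table with the same columns.
#' @export
merge_unique_loci <- function(tables) {
  all <- do.call(rbind, tables)
  if (is.null(all) || nrow(all) == 0) return(all)
  all <- all[order(all$chr, all$start, all$end), , drop = FALSE]
  out <- list()
  cur <- all[1, , drop = FALSE]
  flush <- function(cur) {
    data.frame(lead_snp = cur$lead_snp[which.min(cur$min_p)],
               chr = cur$chr[1], start = min(cur$start), end = max(cur$end),
               n_snps = sum(cur$n_snps), min_p = min(cur$min_p),
               members = paste(unique(unlist(
                 strsplit(cur$members, ","))), collapse = ","),
               features = paste(sort(unique(unlist(
                 strsplit(cur$features, ",")))), collapse = ","))
  }
  for (i in seq_len(nrow(all))[-1]) {
    row <- all[i, , drop = FALSE]
    if (row$chr == cur$chr[1] && row$start <= max(cur$end)) {
      cur <- rbind(cur, row)
    } else {
      out[[length(out) + 1]] <- flush(cur)
      cur <- row
    }
  }
  out[[length(out) + 1]] <- flush(cur)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  cbind(locus = seq_len(nrow(res)), res)
}
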