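## Confirmatory polyvoxel scoring: project raw voxel data of an
## independent sample onto the discovery-sample, SNP-specific multivariate
## effect pattern and test the lead variant against the score.

#' Polyvoxel score for one SNP in a (validation) sample
#'
#' Per subject, `score = sum_k beta_k * v_k' (x - center)`, where the
#' eigenvectors `v_k`, per-PC coefficients `beta_k`, and voxel means all
#' come from the DISCOVERY sample and `x` is the subject's raw voxel data.
#'
#' @param X A `phenotype_volumes` object (or subject x voxel matrix) from
#'   the sample being scored; its voxel grid must match the discovery grid.
#' @param basis The discovery `pc_basis`.
#' @param beta_row Per-PC discovery coefficients for the SNP.
#' @param K_use Number of leading components entering the score (default:
#'   all components of the basis).
#' @return Numeric vector of per-subject scores.
#' @export
polyvoxel_score <- function(X, basis, beta_row,
                            K_use = ncol(basis$vectors)) {
  stopifnot(inherits(basis, "pc_basis"))
  vals <- if (inherits(X, "phenotype_volumes")) {
    if (!is.null(basis$grid_dims) &&
        !identical(as.integer(X$grid_dims), as.integer(basis$grid_dims)))
      stop2("voxel grid does not match the discovery basis")
    X$values
  } else as.matrix(X)
  if (ncol(vals) != nrow(basis$vectors))
    stop2("voxel count does not match the discovery basis")
  Xc <- sweep(vals, 2, basis$center)
  b <- beta_row[seq_len(K_use)]
  b[is.na(b)] <- 0
  drop(Xc %*% (basis$vectors[, seq_len(K_use), drop = FALSE] %*% b))
}

#' Confirmatory association between a dosage and a polyvoxel score
#'
#' Residualizes the dosage and the score on the covariates and computes
#' the marginal correlation t-statistic (identical whichever variable is
#' treated as the response) with a two-sided p-value.
#'
#' @param g Dosage vector (missing values mean-imputed).
#' @param score Polyvoxel score vector.
#' @param Z Covariate data.frame or `NULL`.
#' @return List with `t`, `p`, `df`, and `testable` (FALSE when either
#'   residualized variable has zero variance).
#' @export
confirmatory_test <- function(g, score, Z = NULL) {
  if (length(g) != length(score)) stop2("subject counts differ")
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  D <- covariate_design(Z, n = length(g))
  q <- qr(D)
  gr <- drop(qr.resid(q, cbind(g)))
  sr <- drop(qr.resid(q, cbind(score)))
  df <- length(g) - ncol(D) - 1L
  if (sum(gr^2) < length(g) * 1e-12 || sum(sr^2) < length(g) * 1e-12 ||
      df < 1) {
    return(list(t = NA_real_, p = NA_real_, df = df, testable = FALSE))
  }
  r <- sum(gr * sr) / sqrt(sum(gr^2) * sum(sr^2))
  r <- max(min(r, 1), -1)
  t <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, testable = TRUE)
}

#' Validate discovered loci by confirmatory polyvoxel scoring
#'
#' For each locus lead SNP, builds its polyvoxel score in the validation
#' sample from the discovery eigenvectors and per-PC coefficients, runs
#' the confirmatory association against the lead dosage, and applies a
#' Bonferroni threshold of `0.05 / (number of loci discovered)`.
#'
#' @param loci Locus table from [clump_loci()] (discovery).
#' @param X_val Validation `phenotype_volumes`.
#' @param G_val Validation `genotype_matrix` (matched by SNP id).
#' @param Z_val Validation covariates (or `NULL`).
#' @param basis Discovery `pc_basis`.
#' @param assoc Discovery `per_pc_assoc` (supplies `beta_k` per lead SNP).
#' @param K_use Components entering each score (default: all).
#' @return A validation report data.frame: per locus `lead_snp`, `t`, `p`,
#'   `alpha`, `validated`, `testable`.
#' @export
validate_loci <- function(loci, X_val, G_val, Z_val, basis, assoc,
                          K_use = ncol(basis$vectors)) {
  n_loci <- nrow(loci)
  if (n_loci == 0) {
    return(data.frame(locus = integer(0), lead_snp = character(0),
                      t = numeric(0), p = numeric(0), alpha = numeric(0),
                      validated = logical(0), testable = logical(0)))
  }
  alpha <- 0.05 / n_loci
  rows <- lapply(seq_len(n_loci), function(i) {
    lead <- loci$lead_snp[i]
    gi <- match(lead, G_val$snp)
    ai <- match(lead, assoc$snp)
    if (is.na(gi) || is.na(ai)) {
      return(data.frame(locus = loci$locus[i], lead_snp = lead,
                        t = NA_real_, p = NA_real_, alpha = alpha,
                        validated = NA, testable = FALSE))
    }
    sc <- polyvoxel_score(X_val, basis, assoc$beta[ai, ], K_use = K_use)
    ct <- confirmatory_test(G_val$dosages[, gi], sc, Z_val)
    data.frame(locus = loci$locus[i], lead_snp = lead, t = ct$t, p = ct$p,
               alpha = alpha,
               validated = if (ct$testable) ct$p < alpha else NA,
               testable = ct$testable)
  })
  do.call(rbind, rows)
}
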