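## Regional enrichment: probability-weighted mean of a SNP's back-projected
## voxel coefficients, standardized against a bootstrap null built from the
## association patterns of non-significant SNPs.

#' Probability-weighted regional enrichment score
#'
#' `score = sum_i P_i beta_hat_i / sum_i P_i`: the mean of the voxelwise
#' back-projected coefficients weighted by the region's probability map.
#' Invariant to rescaling `P` by a positive constant.
#'
#' @param beta_map Voxel vector of back-projected coefficients.
#' @param prob_map Voxel vector of region probabilities in `[0, 1]`.
#' @return The weighted mean (finite scalar).
#' @export
enrichment_score <- function(beta_map, prob_map) {
  if (length(beta_map) != length(prob_map)) stop2("voxel counts differ")
  sP <- sum(prob_map)
  if (sP <= 0) stop2("probability map sums to zero")
  sum(prob_map * beta_map) / sP
}

#' Bootstrap null for the enrichment score
#'
#' Resamples whole SNP association maps (with replacement) from the
#' collection of non-significant SNPs -- preserving each map's spatial
#' correlation -- computes the enrichment score of each resample, and
#' returns the null mean and SD.
#'
#' @param nonsig_maps Voxel x SNP matrix (or list of voxel vectors) of
#'   back-projected maps for non-significant SNPs; at least 50 required.
#' @param prob_map Region probability map.
#' @param B Number of bootstrap draws (>= 100; desk-scale default 1000).
#' @param seed Integer seed.
#' @return List with `mu0`, `sigma0`, `B`. Warns when the null is
#'   degenerate (`sigma0 == 0`).
#' @export
bootstrap_null <- function(nonsig_maps, prob_map, B = 1000, seed = 1L) {
  if (is.list(nonsig_maps)) nonsig_maps <- do.call(cbind, nonsig_maps)
  nonsig_maps <- as.matrix(nonsig_maps)
  if (ncol(nonsig_maps) < 50)
    stop2("need at least 50 non-significant SNP maps (got ",
          ncol(nonsig_maps), ")")
  if (B < 100) stop2("B must be >= 100")
  sP <- sum(prob_map)
  if (sP <= 0) stop2("probability map sums to zero")
  scores <- drop(crossprod(nonsig_maps, prob_map)) / sP
  set.seed(seed)
  draws <- scores[sample.int(length(scores), B, replace = TRUE)]
  sigma0 <- sd(draws)
  if (sigma0 == 0) warning("degenerate bootstrap null (sigma0 = 0)")
  list(mu0 = mean(draws), sigma0 = sigma0, B = B)
}

#' Regional enrichment profile of one SNP across an atlas
#'
#' For every region, computes the probability-weighted enrichment score of
#' the SNP's map, the bootstrap null mean/SD from non-significant SNP
#' maps, the z-score `(score - mu0) / sigma0`, a two-sided normal p-value,
#' and the rank by `|z|` (1 = most enriched).
#'
#' @param snp_map Voxel vector, the SNP's back-projected coefficient map.
#' @param nonsig_maps Voxel x SNP matrix of non-significant SNP maps.
#' @param atlas A `region_atlas`.
#' @param B Bootstrap draws per region.
#' @param seed Integer seed.
#' @return Data.frame per region: `region`, `score`, `mu0`, `sigma0`, `z`,
#'   `p`, `rank`, sorted by rank. The top five rows are the headline view.
#' @export
enrichment_profile <- function(snp_map, nonsig_maps, atlas, B = 1000,
                               seed = 1L) {
  stopifnot(inherits(atlas, "region_atlas"))
  nR <- ncol(atlas$P)
  if (nR < 1) stop2("atlas has no regions")
  ## one shared resampling stream so identical regions get identical nulls
  rows <- lapply(seq_len(nR), function(r) {
    P <- atlas$P[, r]
    sc <- enrichment_score(snp_map, P)
    nl <- bootstrap_null(nonsig_maps, P, B = B, seed = seed)
    z <- if (nl$sigma0 > 0) (sc - nl$mu0) / nl$sigma0 else NA_real_
    data.frame(region = atlas$names[r], score = sc, mu0 = nl$mu0,
               sigma0 = nl$sigma0, z = z,
               p = 2 * pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-abs(out$z), ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}
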