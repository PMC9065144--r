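## Tissue-fraction features from per-voxel spherical-harmonic model
## coefficients of a three-compartment diffusion model (restricted,
## hindered, free water).

#' Bundle per-voxel spherical-harmonic coefficients
#'
#' @param restricted0 Numeric vector (or 1-column matrix), the zeroth-order
#'   restricted-compartment coefficient per voxel.
#' @param restricted2 Voxel x 5 matrix of second-order restricted
#'   coefficients.
#' @param restricted4 Voxel x 9 matrix of fourth-order restricted
#'   coefficients.
#' @param hindered Voxel x (>=1) matrix of hindered-compartment
#'   coefficients.
#' @param free0 Numeric vector, the zeroth-order free-water coefficient.
#' @return An object of class `sh_coefficients`.
#' @export
sh_coefficients <- function(restricted0, restricted2, restricted4,
                            hindered, free0) {
  as_mat <- function(x, k, nm) {
    x <- as.matrix(x)
    if (!is.null(k) && ncol(x) != k)
      stop2(nm, " must have ", k, " columns (got ", ncol(x), ")")
    if (any(!is.finite(x))) stop2("non-finite values in ", nm)
    x
  }
  r0 <- as_mat(restricted0, 1L, "restricted0")
  r2 <- as_mat(restricted2, 5L, "restricted2")
  r4 <- as_mat(restricted4, 9L, "restricted4")
  hi <- as_mat(hindered, NULL, "hindered")
  f0 <- as_mat(free0, 1L, "free0")
  nv <- nrow(r0)
  if (any(sapply(list(r2, r4, hi, f0), nrow) != nv))
    stop2("coefficient groups disagree on voxel count")
  structure(list(restricted0 = r0, restricted2 = r2, restricted4 = r4,
                 hindered = hi, free0 = f0),
            class = "sh_coefficients")
}

#' Normalized tissue volume fractions N0, ND, NF
#'
#' Normalizes spherical-harmonic model coefficients into the three
#' unitless tissue-composition features: the restricted isotropic fraction
#' `N0 = |c_r0| / ||c||`, the restricted directional fraction
#' `ND = ||(c_r2, c_r4)|| / ||c||` (Euclidean norm over the second- and
#' fourth-order restricted coefficients, which keeps the feature
#' rotation-invariant and in `[0, 1]`), and the free-water fraction
#' `NF = |c_f0| / ||c||`, where `||c||` is the Euclidean norm over all
#' model coefficients. Voxels with an all-zero coefficient vector are
#' marked invalid rather than divided by zero.
#'
#' @param sh An [sh_coefficients()] set.
#' @return A data.frame with columns `N0`, `ND`, `NF` (each in `[0, 1]`,
#'   `NA` outside the validity mask) and logical `valid`.
#' @export
compute_tissue_fractions <- function(sh) {
  stopifnot(inherits(sh, "sh_coefficients"))
  all_sq <- rowSums(sh$restricted0^2) + rowSums(sh$restricted2^2) +
    rowSums(sh$restricted4^2) + rowSums(sh$hindered^2) + rowSums(sh$free0^2)
  nrm <- sqrt(all_sq)
  valid <- nrm > 0
  safe <- ifelse(valid, nrm, NA_real_)
  out <- data.frame(
    N0 = abs(sh$restricted0[, 1]) / safe,
    ND = sqrt(rowSums(sh$restricted2^2) + rowSums(sh$restricted4^2)) / safe,
    NF = abs(sh$free0[, 1]) / safe,
    valid = valid
  )
  rownames(out) <- NULL
  out
}
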