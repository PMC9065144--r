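## Synthetic cohorts: block-LD genotypes in Hardy-Weinberg proportions,
## spatially smooth low-rank voxel phenotypes with covariate and SNP effects,
## and probabilistic region atlases -- everything downstream is testable
## against the generative parameters returned in `ground_truth`.

#' Configuration for a synthetic imaging-genetics cohort
#'
#' Collects every knob of the data-generating model: genotype panel size and
#' LD structure, voxel grid, latent spatial components, noise level, causal
#' SNP effects and covariate effects.
#'
#' @param n_subjects Number of subjects.
#' @param n_snps Number of biallelic SNPs.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-SNP minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param ld_block_size SNPs per LD block; blocks are mutually independent.
#' @param within_block_r Target Pearson correlation between adjacent SNP
#'   dosages within a block, in `[0, 1)`. Induced through a Gaussian copula
#'   on latent allele variables, so Hardy-Weinberg proportions hold exactly.
#' @param missing_rate Fraction of dosages set missing completely at random.
#' @param grid_dims Integer vector of length 3, the voxel grid.
#' @param n_latent Number of smooth latent spatial components (the low-rank
#'   background structure of the phenotype).
#' @param noise_sd Standard deviation of i.i.d. voxelwise Gaussian noise.
#' @param causal_spec `NULL` or a data.frame with columns `snp` (SNP index),
#'   `region` (region id in the atlas supplied to [simulate_phenotypes()]),
#'   and `beta` (effect per allele, in phenotype SD units); the SNP's voxel
#'   effect map is the region's probability map scaled by `beta`.
#' @param covariate_spec Named numeric vector of effect sizes for the
#'   `age`, `sex` and `gvol` (global-volume analog) covariates, each applied
#'   through its own smooth spatial map on the standardized covariate.
#' @param noise_corr Optional spatial correlation length (voxels) for the
#'   noise field; `0` (default) gives white noise.
#' @param seed Integer seed; identical configs give byte-identical data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects, n_snps,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10L,
                       within_block_r = 0.5,
                       missing_rate = 0,
                       grid_dims = c(10L, 10L, 2L),
                       n_latent = 3L,
                       noise_sd = 1,
                       causal_spec = NULL,
                       covariate_spec = c(age = 0.3, sex = 0.3, gvol = 0.3),
                       noise_corr = 0,
                       seed = 1L) {
  if (n_subjects < 1 || n_snps < 1 || n_latent < 0)
    stop2("counts must be positive")
  if (length(grid_dims) != 3L || any(grid_dims < 1))
    stop2("grid_dims must be 3 positive integers")
  if (ld_block_size < 1) stop2("ld_block_size must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop2("maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop2("missing_rate must be in [0, 1)")
  if (within_block_r < 0 || within_block_r >= 1)
    stop2("within_block_r must be in [0, 1)")
  if (noise_sd < 0) stop2("noise_sd must be nonnegative")
  if (!is.null(causal_spec)) {
    causal_spec <- as.data.frame(causal_spec)
    stopifnot(all(c("snp", "region", "beta") %in% names(causal_spec)))
    if (any(causal_spec$snp < 1 | causal_spec$snp > n_snps))
      stop2("causal SNP index out of range")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
    maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
    within_block_r = within_block_r, missing_rate = missing_rate,
    grid_dims = as.integer(grid_dims), n_latent = as.integer(n_latent),
    noise_sd = noise_sd, causal_spec = causal_spec,
    covariate_spec = covariate_spec, noise_corr = noise_corr,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho,
## via Plackett's identity: d/drho Phi2 = bivariate density at (t1, t2).
binorm_cdf <- function(t1, t2, rho) {
  if (rho == 0) return(pnorm(t1) * pnorm(t2))
  dens <- function(r) {
    exp(-(t1^2 - 2 * r * t1 * t2 + t2^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  pnorm(t1) * pnorm(t2) +
    integrate(Vectorize(dens), 0, rho, rel.tol = 1e-9)$value
}

## latent normal correlation giving Pearson correlation `target` between
## Bernoulli(p1), Bernoulli(p2) threshold indicators
latent_rho <- function(p1, p2, target) {
  if (target == 0) return(0)
  t1 <- qnorm(p1); t2 <- qnorm(p2)
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  f <- function(r) (binorm_cdf(t1, t2, r) - p1 * p2) / denom - target
  upper <- 0.9999
  if (f(upper) < 0) return(upper)  # target unattainable for these MAFs
  uniroot(f, c(0, upper), tol = 1e-7)$root
}

#' Simulate biallelic genotype dosages with block LD
#'
#' Draws two independent haplotypes per subject from a Gaussian copula whose
#' latent variables follow an AR(1) chain within each LD block, so adjacent
#' dosages correlate at `within_block_r` in expectation, blocks are
#' independent, and genotypes are in exact Hardy-Weinberg proportions.
#' Entries are then masked missing completely at random.
#'
#' @param cfg A [sim_config()].
#' @param maf,positions Optional per-SNP minor allele frequencies and
#'   base-pair positions; when supplied (e.g. to share a SNP panel between
#'   discovery and validation draws) they override the config-seeded draw.
#' @param seed Optional seed overriding `cfg$seed` (used for sample splits).
#' @return A `genotype_matrix`: list with `dosages` (subject x SNP, values
#'   0/1/2 or `NA`), `snp`, `chr`, `pos`, `maf` (generating frequencies),
#'   and `block` ids.
#' @export
simulate_genotypes <- function(cfg, maf = NULL, positions = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed %||% cfg$seed)
  n <- cfg$n_subjects; m <- cfg$n_snps
  if (is.null(maf)) maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  if (is.null(positions))
    positions <- cumsum(sample(5000:20000, m, replace = TRUE))
  block <- rep(seq_len(ceiling(m / cfg$ld_block_size)),
               each = cfg$ld_block_size)[seq_len(m)]
  ## latent AR(1) correlations per adjacent within-block pair
  rho <- numeric(m)
  if (cfg$within_block_r > 0 && m > 1) {
    for (j in 2:m) {
      if (block[j] == block[j - 1])
        rho[j] <- latent_rho(maf[j - 1], maf[j], cfg$within_block_r)
    }
  }
  dosages <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1) {
      for (j in 2:m) {
        if (rho[j] > 0)
          z[, j] <- rho[j] * z[, j - 1] + sqrt(1 - rho[j]^2) * z[, j]
      }
    }
    dosages <- dosages + (z < matrix(qnorm(maf), n, m, byrow = TRUE))
  }
  storage.mode(dosages) <- "integer"
  if (cfg$missing_rate > 0) {
    dosages[matrix(runif(n * m) < cfg$missing_rate, n, m)] <- NA_integer_
  }
  structure(list(
    dosages = dosages,
    snp = sprintf("snp%05d", seq_len(m)),
    chr = rep("1", m),
    pos = as.integer(positions),
    maf = maf,
    block = block
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs, %d LD blocks, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$block)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

## separable 3-D Gaussian blur (zero-padded edges, rows renormalized)
gauss_blur_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  for (ax in 1:3) {
    d <- dim(arr)[ax]
    K <- outer(seq_len(d), seq_len(d), function(i, j) dnorm(i - j, sd = sigma))
    K <- K / rowSums(K)
    res <- apply(arr, setdiff(1:3, ax), function(v) K %*% v)
    arr <- switch(ax,
                  res,
                  aperm(res, c(2, 1, 3)),
                  aperm(res, c(2, 3, 1)))
  }
  arr
}

#' Simulate a probabilistic region atlas
#'
#' Places `n_regions` rectangular seeds on the voxel grid and (optionally)
#' blurs them into smooth probability blobs rescaled to peak 1, emulating a
#' probabilistic anatomical atlas.
#'
#' @param grid_dims Integer length-3 voxel grid.
#' @param n_regions Number of regions (>= 1).
#' @param smoothness Gaussian blur sigma in voxels; `0` keeps binary boxes.
#' @param seed Integer seed.
#' @param boxes Optional list of explicit boxes, each a list with integer
#'   vectors `lo` and `hi` (inclusive voxel index ranges per axis); overrides
#'   random placement, e.g. to build disjoint regions for power studies.
#' @return A `region_atlas`: list with `P` (voxel x region probability
#'   matrix, row-major voxel order), `names`, and `grid_dims`.
#' @export
simulate_region_atlas <- function(grid_dims, n_regions, smoothness = 1,
                                  seed = 1L, boxes = NULL) {
  if (n_regions < 1) stop2("n_regions must be >= 1")
  grid_dims <- as.integer(grid_dims)
  set.seed(seed)
  if (is.null(boxes)) {
    boxes <- lapply(seq_len(n_regions), function(i) {
      size <- pmax(1L, sapply(grid_dims, function(d)
        sample(seq_len(max(1L, d %/% 3L)), 1)))
      lo <- sapply(seq_along(grid_dims), function(a)
        sample(seq_len(grid_dims[a] - size[a] + 1L), 1))
      list(lo = lo, hi = lo + size - 1L)
    })
  }
  P <- matrix(0, prod(grid_dims), length(boxes))
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    if (any(b$hi - b$lo + 1L > grid_dims) || any(b$lo < 1) ||
        any(b$hi > grid_dims))
      stop2("region ", i, " does not fit in the grid")
    arr <- array(0, grid_dims)
    arr[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- 1
    if (smoothness > 0) {
      arr <- gauss_blur_3d(arr, smoothness)
      arr <- arr / max(arr)
    }
    P[, i] <- as.vector(arr)
  }
  structure(list(P = P,
                 names = sprintf("region%03d", seq_along(boxes)),
                 grid_dims = grid_dims),
            class = "region_atlas")
}

## smooth unit-SD spatial map used for latent components and covariate maps
smooth_map <- function(grid_dims, sigma = 1.5) {
  arr <- gauss_blur_3d(array(rnorm(prod(grid_dims)), grid_dims), sigma)
  v <- as.vector(arr)
  v / sd(v)
}

#' Simulate voxelwise phenotypes with covariate, latent and SNP effects
#'
#' Generates subject x voxel phenotype values as the sum of covariate
#' effects through smooth spatial maps, causal-SNP effects whose voxel maps
#' follow the atlas region probability maps, smooth low-rank latent spatial
#' components, and Gaussian noise:
#' `y_iv = sum_c gamma_c z_ic m_cv + sum_q beta_q g_iq w_qv +
#'  sum_l u_il b_lv + e_iv`.
#'
#' @param G A `genotype_matrix` (missing dosages are mean-imputed for
#'   generation; missingness exists only to exercise QC).
#' @param atlas A `region_atlas` supplying the causal effect maps `w_q`.
#' @param cfg The [sim_config()] (its `causal_spec` region ids index
#'   `atlas$names` or columns of `atlas$P`).
#' @param seed Optional seed override.
#' @return List with `phenotypes` (`phenotype_volumes`: `values`,
#'   `grid_dims`, `mask`), `covariates` (data.frame: age, sex, gvol, batch,
#'   anc1..anc5), and `ground_truth` (causal spec, voxel effect maps, latent
#'   and covariate maps, per-voxel and variance-weighted average
#'   heritability of the SNP component).
#' @export
simulate_phenotypes <- function(G, atlas, cfg, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(atlas, "region_atlas"),
            inherits(cfg, "sim_config"))
  set.seed((seed %||% cfg$seed) + 1L)
  n <- nrow(G$dosages)
  V <- prod(cfg$grid_dims)
  if (!identical(as.integer(atlas$grid_dims), cfg$grid_dims))
    stop2("atlas grid does not match config grid")

  ## covariates: age uniform, sex Bernoulli(0.5), global-volume analog
  ## normal, 4 equal batches, 5 ancestry axes
  covariates <- data.frame(
    age = runif(n, 45, 80),
    sex = rbinom(n, 1, 0.5),
    gvol = rnorm(n),
    batch = factor(sample(rep_len(paste0("b", 1:4), n))),
    anc1 = rnorm(n), anc2 = rnorm(n), anc3 = rnorm(n),
    anc4 = rnorm(n), anc5 = rnorm(n)
  )

  Y <- matrix(0, n, V)
  cov_maps <- NULL
  cs <- cfg$covariate_spec
  if (length(cs) > 0 && any(cs != 0)) {
    cov_maps <- sapply(names(cs), function(nm) smooth_map(cfg$grid_dims))
    for (i in seq_along(cs)) {
      z <- covariates[[names(cs)[i]]]
      z <- (z - mean(z)) / max(sd(z), 1e-12)
      Y <- Y + cs[i] * z %*% t(cov_maps[, i])
    }
  }

  ## causal SNP effects: effect map = beta * region probability map
  effect_maps <- NULL
  genetic <- matrix(0, n, V)
  if (!is.null(cfg$causal_spec) && nrow(cfg$causal_spec) > 0) {
    qs <- cfg$causal_spec
    effect_maps <- matrix(0, V, nrow(qs))
    for (q in seq_len(nrow(qs))) {
      rid <- qs$region[q]
      ridx <- if (is.character(rid)) match(rid, atlas$names) else as.integer(rid)
      if (is.na(ridx) || ridx < 1 || ridx > ncol(atlas$P))
        stop2("causal region '", rid, "' absent from atlas")
      w <- atlas$P[, ridx]
      g <- G$dosages[, qs$snp[q]]
      if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
      effect_maps[, q] <- qs$beta[q] * w
      genetic <- genetic + g %*% t(effect_maps[, q, drop = FALSE])
    }
    Y <- Y + genetic
  }

  latent_maps <- NULL
  if (cfg$n_latent > 0) {
    latent_maps <- sapply(seq_len(cfg$n_latent),
                          function(l) smooth_map(cfg$grid_dims))
    U <- matrix(rnorm(n * cfg$n_latent), n)
    Y <- Y + U %*% t(latent_maps)
  }

  if (cfg$noise_sd > 0) {
    E <- matrix(rnorm(n * V, sd = cfg$noise_sd), n, V)
    if (cfg$noise_corr > 0) {
      for (i in seq_len(n)) {
        arr <- gauss_blur_3d(array(E[i, ], cfg$grid_dims), cfg$noise_corr)
        E[i, ] <- as.vector(arr) / sd(arr) * cfg$noise_sd
      }
    }
    Y <- Y + E
  }

  var_g <- apply(genetic, 2, var)
  var_y <- apply(Y, 2, var)
  h2_voxel <- ifelse(var_y > 0, var_g / var_y, 0)
  structure_pheno <- structure(list(values = Y, grid_dims = cfg$grid_dims,
                                    mask = rep(TRUE, V)),
                               class = "phenotype_volumes")
  list(
    phenotypes = structure_pheno,
    covariates = covariates,
    ground_truth = list(
      causal = cfg$causal_spec,
      effect_maps = effect_maps,
      covariate_maps = cov_maps,
      latent_maps = latent_maps,
      h2_voxel = h2_voxel,
      avg_h2 = if (sum(var_y) > 0) sum(h2_voxel * var_y) / sum(var_y) else 0
    )
  )
}

#' Simulate a discovery/validation study with a shared SNP panel
#'
#' Draws one SNP panel (frequencies, positions) from the config seed, then
#' two disjoint subject samples from distinct sub-seeds, mirroring a
#' temporal discovery/validation split.
#'
#' @param cfg A [sim_config()] describing the discovery sample.
#' @param atlas A `region_atlas`.
#' @param n_validation Validation sample size (default: same as discovery).
#' @return List with `discovery` and `validation`, each containing
#'   `genotypes`, `phenotypes`, `covariates`, `ground_truth`.
#' @export
simulate_study <- function(cfg, atlas, n_validation = cfg$n_subjects) {
  seeds <- derive_seeds(cfg$seed, 4L)
  set.seed(cfg$seed)
  maf <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  positions <- cumsum(sample(5000:20000, cfg$n_snps, replace = TRUE))
  make <- function(n, sg, sp) {
    c2 <- cfg; c2$n_subjects <- as.integer(n)
    G <- simulate_genotypes(c2, maf = maf, positions = positions, seed = sg)
    sim <- simulate_phenotypes(G, atlas, c2, seed = sp)
    c(list(genotypes = G), sim)
  }
  list(discovery = make(cfg$n_subjects, seeds[1], seeds[2]),
       validation = make(n_validation, seeds[3], seeds[4]))
}
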