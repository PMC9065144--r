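test_that("genotype simulation is deterministic and respects degenerate rates", {
  cfg <- sim_config(200, 30, missing_rate = 0, seed = 11)
  G1 <- simulate_genotypes(cfg)
  G2 <- simulate_genotypes(cfg)
  expect_identical(G1, G2)
  expect_false(anyNA(G1$dosages))
  expect_true(all(G1$dosages %in% 0:2))
  expect_true(all(diff(G1$pos) > 0))

  cfg_miss <- sim_config(500, 30, missing_rate = 0.1, seed = 11)
  Gm <- simulate_genotypes(cfg_miss)
  expect_gt(mean(is.na(Gm$dosages)), 0.07)
  expect_lt(mean(is.na(Gm$dosages)), 0.13)
})

test_that("independent SNPs have adjacent-pair r2 near 1/n and MAF matches binomial error", {
  n <- 10000
  cfg <- sim_config(n, 40, maf_range = c(0.3, 0.4), within_block_r = 0,
                    seed = 21)
  G <- simulate_genotypes(cfg)
  r2 <- sapply(2:40, function(j) cor(G$dosages[, j - 1], G$dosages[, j])^2)
  # E[r2] ~ 1/n for independent SNPs; mean over 39 pairs, 3 MC SDs
  expect_lt(abs(mean(r2) - 1 / n), 3 * sd(r2) / sqrt(length(r2)) + 1 / n)

  cfg5 <- sim_config(n, 20, maf_range = c(0.5, 0.5), within_block_r = 0,
                     seed = 22)
  G5 <- simulate_genotypes(cfg5)
  af <- colMeans(G5$dosages) / 2
  expect_true(all(abs(af - 0.5) < 3 * sqrt(0.25 / (2 * n))))
})

test_that("block LD hits the target adjacent dosage correlation in expectation", {
  cfg <- sim_config(4000, 50, maf_range = c(0.1, 0.5), ld_block_size = 10,
                    within_block_r = 0.5, seed = 31)
  G <- simulate_genotypes(cfg)
  adj <- sapply(2:50, function(j)
    if (G$block[j] == G$block[j - 1]) cor(G$dosages[, j - 1], G$dosages[, j])
    else NA_real_)
  expect_lt(abs(mean(adj, na.rm = TRUE) - 0.5), 0.05)
  # blocks independent: cross-block adjacent pairs uncorrelated
  crossb <- adj[is.na(adj)]
  expect_equal(length(crossb), 4)
})

test_that("genotypes are in Hardy-Weinberg proportions", {
  cfg <- sim_config(1000, 500, within_block_r = 0, missing_rate = 0,
                    seed = 41)
  G <- simulate_genotypes(cfg)
  hwe_p <- variant_filters(G)$hwe_p
  expect_gte(mean(hwe_p > 0.001), 0.99)
})

test_that("atlas maps are in [0,1], deterministic, and binary boxes at zero smoothness", {
  a0 <- simulate_region_atlas(c(6L, 6L, 3L), 1, smoothness = 0, seed = 5)
  expect_true(all(a0$P %in% c(0, 1)))
  expect_gt(sum(a0$P), 0)

  a1 <- simulate_region_atlas(c(6L, 6L, 3L), 4, smoothness = 1.5, seed = 6)
  a2 <- simulate_region_atlas(c(6L, 6L, 3L), 4, smoothness = 1.5, seed = 6)
  expect_identical(a1, a2)
  expect_true(all(a1$P >= 0 & a1$P <= 1))
  expect_true(all(colSums(a1$P > 0) >= 1))

  expect_error(simulate_region_atlas(c(4L, 4L, 2L), 1, boxes = list(
    list(lo = c(1, 1, 1), hi = c(9, 2, 2)))), "fit")
})

test_that("pure-noise phenotypes have unit voxel variance and zero effects give low rank", {
  cfg <- sim_config(400, 10, grid_dims = c(5L, 5L, 2L), n_latent = 0,
                    noise_sd = 1, covariate_spec = c(age = 0, sex = 0,
                                                     gvol = 0), seed = 51)
  G <- simulate_genotypes(cfg)
  atlas <- simulate_region_atlas(cfg$grid_dims, 2, seed = 3)
  sim <- simulate_phenotypes(G, atlas, cfg)
  v <- apply(sim$phenotypes$values, 2, var)
  se <- sqrt(2 / (400 - 1))  # SD of a sample variance of N(0,1)
  expect_true(all(abs(v - 1) < 3.5 * se))

  cfg_r <- sim_config(50, 10, grid_dims = c(5L, 5L, 2L), n_latent = 1,
                      noise_sd = 0, covariate_spec = c(age = 0, sex = 0,
                                                       gvol = 0), seed = 52)
  sim_r <- simulate_phenotypes(G <- simulate_genotypes(cfg_r), atlas, cfg_r)
  expect_equal(qr(sim_r$phenotypes$values)$rank, 1)
})

test_that("voxelwise regression recovers the causal effect map", {
  grid <- c(6L, 6L, 2L)
  atlas <- simulate_region_atlas(grid, 1, smoothness = 0, seed = 8)
  cfg <- sim_config(4000, 5, grid_dims = grid, n_latent = 0, noise_sd = 1,
                    covariate_spec = c(age = 0, sex = 0, gvol = 0),
                    causal_spec = data.frame(snp = 3, region = 1,
                                             beta = 0.5),
                    seed = 61)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, atlas, cfg)
  g <- G$dosages[, 3]
  region <- which(atlas$P[, 1] > 0)
  ym <- rowMeans(sim$phenotypes$values[, region, drop = FALSE])
  f <- lm(ym ~ g)
  est <- coef(f)[["g"]]
  se <- summary(f)$coefficients["g", "Std. Error"]
  target <- 0.5 * mean(atlas$P[region, 1])
  expect_lt(abs(est - target), 3 * se)

  # voxelwise OLS recovers beta * w per voxel within 3 SEs (effect-map fidelity)
  bias <- sapply(seq_len(ncol(sim$phenotypes$values)), function(v) {
    fv <- summary(lm(sim$phenotypes$values[, v] ~ g))$coefficients
    (fv["g", "Estimate"] - 0.5 * atlas$P[v, 1]) / fv["g", "Std. Error"]
  })
  expect_lt(max(abs(bias)), 4)

  expect_error(simulate_phenotypes(G, atlas,
    sim_config(4000, 5, grid_dims = grid,
               causal_spec = data.frame(snp = 1, region = 7, beta = 1),
               seed = 1)), "absent")
})

test_that("study split shares the SNP panel but draws disjoint samples", {
  cfg <- sim_config(100, 20, seed = 71,
                    causal_spec = data.frame(snp = 2, region = 1, beta = 0.3))
  atlas <- simulate_region_atlas(cfg$grid_dims, 2, seed = 9)
  st <- simulate_study(cfg, atlas, n_validation = 60)
  expect_identical(st$discovery$genotypes$pos, st$validation$genotypes$pos)
  expect_identical(st$discovery$genotypes$maf, st$validation$genotypes$maf)
  expect_equal(nrow(st$validation$genotypes$dosages), 60)
  expect_false(identical(st$discovery$genotypes$dosages[1:60, ],
                         st$validation$genotypes$dosages))
})
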