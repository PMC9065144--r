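test_that("PCA basis is orthonormal, sorted, sign-fixed and reconstructs the data", {
  set.seed(2)
  n <- 30; V <- 12
  Y <- matrix(rnorm(n * V), n)
  K <- 12
  b <- fit_pca(Y, K)
  expect_equal(crossprod(b$vectors), diag(K), tolerance = 1e-8)
  expect_true(all(diff(b$values) <= 1e-12))
  expect_true(all(sapply(seq_len(K), function(k) {
    j <- which.max(abs(b$vectors[, k])); b$vectors[j, k] > 0
  })))
  # full-rank reconstruction identity
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_equal(b$scores %*% t(b$vectors), Yc, tolerance = 1e-8)

  # rank-1 data: first PC explains all variance
  u <- rnorm(n); v <- rnorm(V)
  b1 <- fit_pca(u %*% t(v), 2)
  expect_equal(b1$cum_var[1], 1, tolerance = 1e-10)

  expect_error(fit_pca(Y, n), "K must be")
})

test_that("residualize matches the explicit OLS oracle", {
  set.seed(3)
  M <- matrix(rnorm(12), 6, 2)
  Z <- data.frame(z = rnorm(6))
  R <- residualize(M, Z)
  oracle <- apply(M, 2, function(y) resid(lm(y ~ Z$z)))
  expect_equal(unname(R), unname(oracle), tolerance = 1e-10)
  # orthogonal to covariates
  expect_lt(max(abs(crossprod(cbind(1, Z$z), R))), 1e-8)

  # intercept only = column centering
  expect_equal(residualize(M), sweep(M, 2, colMeans(M)), tolerance = 1e-12)
  # M equal to a covariate column residualizes to ~0
  expect_lt(max(abs(residualize(cbind(Z$z), Z))), 1e-10)
  # rank-deficient design errors and names the collinear column
  Zbad <- data.frame(a = 1:6, b = 2 * (1:6))
  expect_error(residualize(M, Zbad), "b")
})

test_that("per-PC Wald statistics equal full-design OLS t-statistics", {
  set.seed(4)
  n <- 8
  Y <- matrix(rnorm(n * 6), n)
  Z <- data.frame(z1 = rnorm(n), z2 = rnorm(n))
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  G <- make_gm(cbind(g))
  b <- fit_pca(Y, 3)
  a <- per_pc_wald(b, G, Z)
  t_lm <- sapply(1:3, function(k)
    summary(lm(b$scores[, k] ~ g + z1 + z2,
               data = Z))$coefficients["g", "t value"])
  expect_equal(unname(a$W[1, ]), t_lm, tolerance = 1e-8)
  expect_equal(a$df, n - 3 - 1)

  # constant dosage is flagged, W missing
  Gc <- make_gm(cbind(g, rep(1, n)))
  ac <- per_pc_wald(b, Gc, Z)
  expect_true(ac$flagged[2])
  expect_true(all(is.na(ac$W[2, ])))
  expect_false(ac$flagged[1])
})

test_that("per-PC Wald statistics are standard normal under the null", {
  cfg <- sim_config(2000, 200, within_block_r = 0, grid_dims = c(5L, 5L, 2L),
                    seed = 19)
  G <- simulate_genotypes(cfg)
  atlas <- simulate_region_atlas(cfg$grid_dims, 2, seed = 2)
  sim <- simulate_phenotypes(G, atlas, cfg)
  b <- fit_pca(sim$phenotypes, 20)
  a <- per_pc_wald(b, G, sim$covariates)
  W <- as.vector(a$W)
  expect_lt(abs(mean(W)), 3 * sqrt(1 / length(W)))
  expect_lt(abs(var(W) - 1), 0.1)
})

test_that("chi-squared sum rule matches closed forms and is uniform under the null", {
  cs0 <- combine_sum(rep(0, 4))
  expect_equal(cs0$stat, 0)
  expect_equal(cs0$p, 1)

  cs <- combine_sum(c(1, 2))
  expect_equal(cs$stat, 5)
  expect_equal(cs$p, exp(-2.5), tolerance = 1e-12)

  # missing W drops the PC and reduces df
  csna <- combine_sum(c(1, 2, NA))
  expect_equal(csna$df, 2)
  expect_equal(csna$p, exp(-2.5), tolerance = 1e-12)

  expect_error(combine_sum(numeric(0)), "empty")

  set.seed(6)
  Wnull <- matrix(rnorm(2000 * 20), 2000)
  p <- combine_sum(Wnull)$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("global-local Fisher combination matches the chi2_4 closed form", {
  # p_head = p_tail = 0.5: X = -2(log .5 + log .5) = 2.77259
  w <- sqrt(qchisq(0.5, 1, lower.tail = FALSE))
  gl <- combine_global_local(c(w, w), 1)
  X <- -2 * (log(0.5) + log(0.5))
  expect_equal(gl$stat, X, tolerance = 1e-10)
  expect_equal(gl$p, (1 + X / 2) * exp(-X / 2), tolerance = 1e-10)

  # p_head = p_tail = 1 -> X = 0, p = 1
  gl0 <- combine_global_local(c(0, 0), 1)
  expect_equal(gl0$stat, 0)
  expect_equal(gl0$p, 1)

  # C >= K falls back to the full sum with a warning
  expect_warning(glf <- combine_global_local(c(1, 2), 5), "full sum")
  expect_equal(glf$p, exp(-2.5), tolerance = 1e-12)

  # null uniformity at C = 5, K = 20
  set.seed(7)
  Wnull <- matrix(rnorm(2000 * 20), 2000)
  p <- combine_global_local(Wnull, 5)$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("run_cpc picks the best rule and applies the multiplicity-corrected threshold", {
  expect_equal(cpc_alpha(4, 3), 5e-8 / 12)
  expect_equal(cpc_alpha(4, 3), 4.2e-9, tolerance = 0.01)

  set.seed(8)
  W <- matrix(rnorm(50 * 10), 50)
  W[1, ] <- W[1, ] + 3  # strong signal across all PCs
  a <- structure(list(beta = W, se = W * 0 + 1, W = W, df = 100,
                      snp = sprintf("s%02d", 1:50),
                      flagged = rep(FALSE, 50)),
                 class = "per_pc_assoc")
  res <- run_cpc(a, cut_points = c(2, 5), alpha = 1e-6)
  pm <- as.matrix(res[, c("p_sum", "p_gl2", "p_gl5")])
  expect_equal(res$best_p, apply(pm, 1, min))
  expect_true(res$significant[1])
  expect_true(all(res$significant == (res$best_p < 1e-6)))
  expect_error(run_cpc(a, cut_points = c(10)), "1 <= C < K")
})

test_that("back-projection is the change-of-basis identity", {
  set.seed(9)
  Y <- matrix(rnorm(40 * 5), 40)
  b <- fit_pca(Y, 5)
  # unit vector on PC1 returns eigenvector 1
  expect_equal(backproject(b, c(1, 0, 0, 0, 0)), b$vectors[, 1])
  # linearity
  b1 <- rnorm(5); b2 <- rnorm(5)
  expect_equal(backproject(b, b1 + b2),
               backproject(b, b1) + backproject(b, b2), tolerance = 1e-12)
  # full-rank: back-projected per-PC coefficients equal voxelwise OLS slopes
  g <- rbinom(40, 2, 0.4)
  a <- per_pc_wald(b, make_gm(cbind(g)), NULL)
  map <- backproject(b, a$beta[1, ])
  ols <- apply(Y, 2, function(y) coef(lm(y ~ g))[["g"]])
  expect_equal(map, unname(ols), tolerance = 1e-8)
})

test_that("the combined statistic approximates the rotation-invariant subspace form", {
  # The exactly rotation-invariant statistic is the projection quadratic
  # form g~' S(S'S)^-1 S' g~ (times df); the chi-squared sum of per-PC Wald
  # statistics coincides with it when scores are in-sample orthogonal and
  # effects are small, which the PCA basis guarantees approximately.
  # null covariate effects: with phenotype-covariate loadings, residualizing
  # the scores breaks their in-sample orthogonality and the marginal-Wald sum
  # departs from the subspace form by construction, not by error
  cfg <- sim_config(500, 30, grid_dims = c(5L, 5L, 2L), seed = 23,
                    covariate_spec = c(age = 0, sex = 0, gvol = 0))
  G <- simulate_genotypes(cfg)
  atlas <- simulate_region_atlas(cfg$grid_dims, 2, seed = 2)
  sim <- simulate_phenotypes(G, atlas, cfg)
  b <- fit_pca(sim$phenotypes, 10)
  Z <- sim$covariates
  a <- per_pc_wald(b, G, Z)
  T_sum <- combine_sum(a$W)$stat

  quad_form <- function(scores) {
    Sr <- residualize(scores, Z)
    Dr <- residualize(G$dosages, Z)
    sapply(seq_len(ncol(Dr)), function(j) {
      g <- Dr[, j]
      fit <- qr.fitted(qr(Sr), g)
      a$df * sum(fit^2) / sum(g^2)
    })
  }
  Q0 <- quad_form(b$scores)
  R <- qr.Q(qr(matrix(rnorm(100), 10)))
  Q1 <- quad_form(b$scores %*% R)
  expect_equal(Q1, Q0, tolerance = 1e-8)          # exact invariance
  expect_lt(max(abs(T_sum - Q0) / Q0), 0.15)      # close agreement
  expect_gt(cor(T_sum, Q0), 0.99)
})

test_that("power is monotone in effect size and the fit object prints", {
  mean_stat <- function(beta) {
    stats <- sapply(1:20, function(s) {
      grid <- c(4L, 4L, 2L)
      atlas <- simulate_region_atlas(grid, 1, smoothness = 0, seed = 55)
      cfg <- sim_config(300, 5, grid_dims = grid, n_latent = 1,
                        causal_spec = data.frame(snp = 3, region = 1,
                                                 beta = beta),
                        seed = 100 + s)
      G <- simulate_genotypes(cfg)
      sim <- simulate_phenotypes(G, atlas, cfg)
      fit <- cpc_gwas(sim$phenotypes, G, sim$covariates, K = 8,
                      cut_points = c(3))
      fit$result$stat_sum[3]
    })
    mean(stats)
  }
  expect_gt(mean_stat(0.4), mean_stat(0.1))

  grid <- c(4L, 4L, 2L)
  atlas <- simulate_region_atlas(grid, 1, smoothness = 0, seed = 55)
  cfg <- sim_config(200, 5, grid_dims = grid, seed = 7)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, atlas, cfg)
  fit <- cpc_gwas(sim$phenotypes, G, sim$covariates, K = 8, cut_points = 3)
  expect_output(print(fit), "Combined-principal-component")
  expect_output(summary(fit), "Top SNPs")
  expect_equal(dim(coef(fit)), c(5, 8))
})
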