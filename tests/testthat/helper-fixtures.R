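# in-code fixtures shared across test files

make_gm <- function(dosages, pos = NULL, chr = NULL, block = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  structure(list(
    dosages = dosages,
    snp = sprintf("s%03d", seq_len(m)),
    chr = chr %||% rep("1", m),
    pos = as.integer(pos %||% (seq_len(m) * 1e5)),
    maf = colMeans(dosages, na.rm = TRUE) / 2,
    block = block %||% seq_len(m)
  ), class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two disjoint corner boxes on an 8x8x2 grid
recovery_atlas <- function() {
  simulate_region_atlas(c(8L, 8L, 2L), 2, smoothness = 1, seed = 99,
                        boxes = list(list(lo = c(1, 1, 1), hi = c(3, 3, 1)),
                                     list(lo = c(6, 6, 2), hi = c(8, 8, 2))))
}

# one replicate of the causal-SNP recovery study: returns discovery flag,
# top-ranked region, and the fitted objects for reuse
recovery_replicate <- function(seed, beta = 0.5, n = 2000, B = 1000) {
  atlas <- recovery_atlas()
  cfg <- sim_config(n, 60, maf_range = c(0.2, 0.4), ld_block_size = 10,
                    within_block_r = 0.3, grid_dims = c(8L, 8L, 2L),
                    n_latent = 3, noise_sd = 1,
                    causal_spec = data.frame(snp = 30, region = 1,
                                             beta = beta),
                    seed = seed)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(G, atlas, cfg)
  fit <- cpc_gwas(sim$phenotypes, G, sim$covariates, K = 20,
                  cut_points = c(5, 10), alpha = cpc_alpha(4, 3))
  nonsig <- which(!fit$result$significant & seq_len(60) != 30)
  if (length(nonsig) < 50)
    nonsig <- setdiff(order(fit$result$best_p, decreasing = TRUE), 30)[1:55]
  maps <- fit$basis$vectors %*% t(fit$assoc$beta[nonsig, , drop = FALSE])
  snp_map <- backproject(fit$basis, fit$assoc$beta[30, ])
  prof <- enrichment_profile(snp_map, maps, atlas, B = B, seed = seed)
  list(discovered = fit$result$significant[30],
       top_region = prof$region[prof$rank == 1],
       fit = fit, atlas = atlas, sim = sim, G = G, profile = prof)
}
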