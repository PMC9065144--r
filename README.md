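# cpcgwas

Multivariate GWAS of voxelwise brain phenotypes via combined principal
components, in R.

## What this is for

Whole-brain voxelwise phenotypes — here the diffusion-MRI tissue-composition
fractions N0 (restricted isotropic, cell bodies), ND (restricted
directional, axons/dendrites) and NF (free water), each a
spherical-harmonic coefficient group normalized by the Euclidean norm of
all model coefficients — are far too high dimensional for voxel-by-voxel
GWAS. `cpcgwas` is for statistical geneticists and imaging-genetics groups
who want the combined-principal-components (CPC) approach as a tested,
reusable pipeline:

1. **Discovery** (`cpc_gwas()`): PCA of the subject × voxel matrix;
   covariate-adjusted per-PC Wald statistics `W_k = β_k / se_k` for every
   SNP; the omnibus statistic `T = Σ W_k² ~ χ²_K` under the null (PCs are
   orthogonal, so the `W_k` are independent), plus global–local variants
   that split the PCs at a cut point C and combine the head and tail block
   p-values with Fisher's method (`X = −2(log p_head + log p_tail) ~ χ²₄`).
   The default genome-wide threshold corrects for the rule search and the
   three features: `5e-8 / 12 ≈ 4.2e-9`.
2. **Loci** (`variant_filters()`, `clump_loci()`, `merge_unique_loci()`):
   MAF/HWE/missingness QC, then greedy clumping of significant SNPs around
   smallest-p leads by LD (r² > 0.1) or distance (≤ 250 kb), and merging of
   overlapping loci across features.
3. **Validation** (`polyvoxel_score()`, `validate_loci()`): per-subject
   polyvoxel scores `Σ β_k v_kᵀ x` built entirely from discovery-sample
   eigenvectors, coefficients and centering, tested against the lead dosage
   in an independent sample with Bonferroni correction over loci.
4. **Enrichment** (`backproject()`, `enrichment_profile()`): the SNP's
   per-PC coefficients back-projected to a voxel map, scored per atlas
   region as the probability-weighted mean `Σ P_i β̂_i / Σ P_i`, and
   standardized against a bootstrap null that resamples whole
   non-significant-SNP maps.
5. **Genome-wide summaries** (`compute_ld_scores()`, `ldsc_h2()`,
   `average_h2()`, `scaled_chi2()`, `block_profile()`, `overlap_rho()`):
   LD-score-regression heritability per PC with block-jackknife SEs, its
   eigenvalue-weighted average, the K-df statistic rescaled to unit null
   mean for stratified LDSC use, and trait–trait overlap as the Spearman
   correlation of per-LD-block mean −log₁₀ p.

A synthetic-cohort generator (`sim_config()`, `simulate_study()`,
`simulate_region_atlas()`, `simulate_phenotypes()`) produces block-LD
genotypes in exact Hardy–Weinberg proportions, spatially structured voxel
phenotypes with known causal effects, and discovery/validation splits, so
the whole pipeline runs and is tested without any cohort data.
`run_discovery()` / `run_validation()` orchestrate the stages with config
hashing, manifests and reproducible outputs; readers/writers cover VCF,
PLINK-style TSV, and NIfTI volumes.

## Worked example

```r
library(cpcgwas)

atlas <- simulate_region_atlas(c(8L, 8L, 2L), 2, smoothness = 1, seed = 99,
  boxes = list(list(lo = c(1, 1, 1), hi = c(3, 3, 1)),
               list(lo = c(6, 6, 2), hi = c(8, 8, 2))))
cfg <- sim_config(2000, 60, maf_range = c(0.2, 0.4), within_block_r = 0.3,
                  grid_dims = c(8L, 8L, 2L),
                  causal_spec = data.frame(snp = 30, region = 1, beta = 0.5),
                  seed = 1)
st  <- simulate_study(cfg, atlas, n_validation = 2000)
d   <- st$discovery

fit <- cpc_gwas(d$phenotypes, d$genotypes, d$covariates, K = 20,
                cut_points = c(5, 10), alpha = cpc_alpha(4, 3))
fit
#> Combined-principal-component multivariate GWAS
#>   feature: pheno | subjects: 2000 | SNPs: 60 | PCs: 20 (83.1% variance)
#>   rules: sum + global-local cuts {5, 10} | alpha = 4.17e-09
#>   significant SNPs: 1
```

The one significant SNP is the planted causal variant; clumping puts it at
the head of a locus and the independent sample confirms it:

```r
loci <- clump_loci(fit$summary_stats, d$genotypes, p_thresh = fit$alpha)
loci[, c("locus", "lead_snp", "start", "end", "min_p")]
#>   locus lead_snp  start    end        min_p
#> 1     1 snp00030 392366 392366 1.163907e-81

v <- st$validation
validate_loci(loci, v$phenotypes, v$genotypes, v$covariates,
              fit$basis, fit$assoc)
#>   locus lead_snp        t           p alpha validated testable
#> 1     1 snp00030 4.527653 6.31757e-06  0.05      TRUE     TRUE
```

`min_p` is the best combined p-value in the locus; `t` is the confirmatory
association between the validation dosages and the polyvoxel score built
from discovery weights — validated at the Bonferroni threshold. Enrichment
then localizes the signal: the causal effect map was region 1's
probability map, and region 1 tops the ranking:

```r
nonsig <- which(!fit$result$significant)
maps <- fit$basis$vectors %*% t(coef(fit)[nonsig, , drop = FALSE])
enrichment_profile(backproject(fit$basis, coef(fit)[30, ]),
                   maps, atlas, B = 1000, seed = 1)
#>     region     score         mu0     sigma0        z         p rank
#>  region001 0.1486082  0.02577205 0.07986274 1.538090 0.1240265    1
#>  region002 0.0534532 -0.01937993 0.05243648 1.388978 0.1648394    2
```

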