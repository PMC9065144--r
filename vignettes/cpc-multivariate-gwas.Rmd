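---
title: "Multivariate GWAS of voxelwise brain phenotypes with combined principal components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate GWAS of voxelwise brain phenotypes with combined principal components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcgwas)
```

## The problem

Voxelwise imaging phenotypes are very high dimensional: a whole-brain map of
a tissue-composition feature easily has 10^5 to 10^6 voxels per subject.
Running a separate GWAS per voxel wastes power (massive multiple testing,
strong spatial correlation) and localizing a variant's effect by per-voxel
association maps is unreliable when effects are spatially distributed.
`cpcgwas` implements the alternative this package is built around: compress
the voxel data into principal components (PCs), test each variant against
every PC, and combine the per-PC evidence into one closed-form omnibus test
per variant — the combined-principal-components (CPC) statistic — followed
by confirmatory validation in an independent sample and a regional
enrichment analysis that maps the multivariate signal back onto anatomy.

The phenotypes the pipeline was designed for are the three restriction-
spectrum-imaging tissue fractions: N0 (restricted isotropic diffusion, cell
bodies), ND (restricted directional diffusion, axons and dendrites) and NF
(free water). `compute_tissue_fractions()` produces them from per-voxel
spherical-harmonic model coefficients: each is a coefficient (or the
Euclidean norm of a coefficient group) divided by the Euclidean norm of all
model coefficients, hence unitless and in [0, 1]. The wording "sum of
second and fourth-order coefficients" for ND is implemented as the
Euclidean norm over those coefficients rather than an algebraic sum: a raw
signed sum is not rotation invariant and can leave [0, 1], while the norm
keeps both properties (a design choice this package makes explicitly; the
algebraic-sum reading would violate the stated range).

## The discovery model

Let $Y$ be the centered subject-by-voxel matrix, with eigenvectors $v_k$,
eigenvalues $\lambda_k$, and subject scores $s_k = Y v_k$. For each variant
with dosage $g$ and covariates $Z$ (age, sex, a global-volume analog,
batch, genetic-ancestry axes), both $g$ and each $s_k$ are residualized on
$Z$, and the marginal regression gives the Wald statistic
$W_k = \hat\beta_k / \mathrm{se}(\hat\beta_k)$. By Frisch–Waugh this equals
the full-design multiple-regression t-statistic, and it is identical
whichever side is treated as the response — which is why "the SNP was
regressed on the PC scores" and "the score was regressed on the SNP"
describe the same statistic.

Because PCA scores are orthogonal in sample, the $W_k$ are independent and
approximately standard normal under the null, so

$$T = \sum_{k=1}^{K} W_k^2 \sim \chi^2_K .$$

The *global–local* variants split the PCs at a cut point $C$ into a head
(the leading $C$ PCs, carrying global spatial structure) and a tail,
compute the $\chi^2$ sum p-value of each block, and combine the two with
Fisher's method, $X = -2(\log p_{head} + \log p_{tail}) \sim \chi^2_4$.
The exact global–local construction is not uniquely pinned down by the
source literature; this head/tail Fisher form is one faithful reading and
is isolated in `combine_global_local()` so alternatives can be swapped.
Both block p-values are computed in log space so genome-wide tails do not
underflow.

Searching over combination rules costs multiplicity: with four cut points
and three tissue features the default genome-wide threshold is
$5 \times 10^{-8} / 12 \approx 4.2 \times 10^{-9}$ (`cpc_alpha(4, 3)`).

A caution on a tempting-but-false invariance: $T$ is *not* invariant to
arbitrary orthogonal rotations of the components. The exactly invariant
object is the subspace quadratic form
$\tilde g^\top S (S^\top S)^{-1} S^\top \tilde g$, which $T$ approximates
when the scores are in-sample orthogonal (as PCA scores are) and effects
are small. After residualizing scores on covariates that the phenotypes
actually load on, in-sample orthogonality is slightly broken and the
approximation degrades; the property test therefore checks the invariant
form exactly and the approximation under null covariate effects.

## Loci, validation, enrichment

**Clumping** (`clump_loci()`): significant variants are grouped greedily
around the smallest-p lead; a variant joins the locus if it is in LD with
the lead ($r^2 > 0.1$) *or* within 250 kb of it. The OR reading is chosen
because LD pruning and positional clumping are described as applied
jointly to collapse signals; the window is lead-to-member. Ties in p are
broken by position then id, making the output invariant to input row
order. Loci from different features whose ranges overlap are unioned by
`merge_unique_loci()`.

**Polyvoxel validation** (`polyvoxel_score()`, `validate_loci()`): for a
discovered lead SNP, each validation subject gets the scalar score
$\sum_k \beta_k v_k^\top x$, with $\beta_k$, $v_k$ and the centering means
all taken from the discovery sample. Regressing the validation dosage on
this score tests whether the discovery-estimated multivariate effect
pattern replicates; the per-locus threshold is $0.05$ Bonferroni-divided
by the number of discovered loci. All $K$ components enter the score by
default (`K_use` is exposed); a covariate-free in-sample identity,
$\mathrm{cov}(g, \mathrm{score}) = \mathrm{var}(g) \sum_k \beta_k^2$,
pins the implementation down exactly. Family-relatedness random effects
are not implemented: the confirmatory regression is fixed-effects with
covariates, a documented limitation for family-structured samples.

**Regional enrichment** (`enrichment_profile()`): the per-PC coefficients
of a significant SNP are back-projected to a voxel map
$\hat\beta_i = \sum_k \beta_k v_{ki}$, and for each region with
probability map $P$ the enrichment score is the probability-weighted mean
$\sum_i P_i \hat\beta_i / \sum_i P_i$ — signed, exactly as defined; signed
weighting can cancel, so the score is kept as printed rather than
silently switched to $|\hat\beta|$. The null is built by resampling whole
non-significant-SNP maps with replacement (preserving each map's spatial
correlation — resampling voxels would destroy it), giving a mean
$\mu_0$ and SD $\sigma_0$, a z-score $(score - \mu_0)/\sigma_0$, and a
two-sided normal p. One shared resampling stream is used across regions so
identical regions receive identical nulls. Null SNPs are drawn genome-wide
without allele-frequency matching.

**Genome-wide summaries**: `compute_ld_scores()` sums dosage $r^2$ within
a positional window (self included, so $\ell \ge 1$); `ldsc_h2()` fits
$E[\chi^2_j] = 1 + n h^2 \ell_j / M$ by unweighted least squares with a
delete-one-block jackknife SE (the original software's iterative weighting
is out of scope); `average_h2()` forms the eigenvalue-weighted average
$\sum_k \lambda_k h^2_k / \sum_k \lambda_k$, the average heritability of
the high-dimensional phenotype; `scaled_chi2()` divides the $K$-df
combined statistic by $K$ so its null mean is 1, the convention expected
by stratified LD-score regression (the literature says only "rescaled";
$1/K$ is the convention this package commits to, isolated in one
function); `block_profile()` + `overlap_rho()` compare two traits by the
Spearman correlation of per-LD-block mean $-\log_{10} p$ (capped at 320
against underflow), with ties mid-ranked and the t-approximation p.

## The synthetic cohort generator

Every stage is testable without cohort data because `sim_config()` /
`simulate_study()` generate data with known ground truth:

* **Genotypes.** Per-SNP minor allele frequencies uniform on `maf_range`;
  within each block of `ld_block_size` SNPs a Gaussian copula with a
  latent AR(1) chain induces LD, and the latent correlation of each
  adjacent pair is solved numerically (Plackett's identity plus
  root-finding) so the *dosage* correlation matches `within_block_r` in
  expectation. The two haplotypes are independent draws, so genotypes are
  in exact Hardy–Weinberg proportions by construction. Missingness is
  completely at random — it exists to exercise QC, nothing else (when a
  causal dosage is missing, generation uses its mean-imputed value).
* **Phenotypes.** $y_{iv} = \sum_c \gamma_c z_{ic} m_{cv} + \sum_q
  \beta_q g_{iq} w_{qv} + \sum_l u_{il} b_{lv} + \varepsilon_{iv}$:
  covariate effects through smooth unit-SD spatial maps, causal SNP
  effects whose voxel maps $w_q$ are region probability maps from the
  atlas, smooth latent components for low-rank background structure, and
  white Gaussian noise (the default; spatially correlated noise is
  exposed via `noise_corr` since the true noise structure of registered
  voxel data is unknown). Covariates are age ~ U(45, 80), sex ~
  Bernoulli(0.5), a standard-normal global-volume analog, four equal
  batches and five ancestry axes; default covariate effect sizes are 0.3
  SD — large enough that broken covariate adjustment fails the null
  calibration tests.
* **Atlas.** Rectangular seeds blurred into probability blobs rescaled to
  peak 1; explicit boxes can be supplied to build disjoint regions for
  power studies.
* **Splits.** `simulate_study()` draws one SNP panel and two disjoint
  subject samples from distinct sub-seeds, mirroring a temporal
  discovery/validation split.

What the generator does *not* emulate: realistic LD from reference
panels, relatedness or family structure, site/scanner batch effects with
spatial signatures, or non-Gaussian voxel noise. Passing tests therefore
demonstrate the statistical machinery on data satisfying the model's
assumptions, not robustness to everything real cohorts do.

## Problem sizes and numerical choices

Desk-scale defaults are deliberate: $K = 50$ components (tests mostly use
20) instead of thousands, enrichment bootstrap $B = 1000$ instead of tens
of thousands, grids of a few hundred voxels instead of $10^6$. These are
the package's chosen test-bed sizes; every size is a function argument.
Other choices worth knowing:

* PCA sign convention: each eigenvector's largest-magnitude loading is
  positive, so bases are reproducible.
* Per-SNP missing dosages are mean-imputed before association (standard
  dosage-GWAS practice).
* A SNP whose residualized dosage variance is ~0 is flagged and its
  statistics set missing rather than producing infinite Wald values; a
  monomorphic SNP trivially passes HWE (expected counts of zero are a
  perfect fit) and is removed by the MAF filter instead.
* HWE is a 1-df chi-squared without continuity correction, appropriate
  for common variants at the sample sizes simulated.
* Missing per-PC Wald entries drop the PC and reduce the chi-squared df.
* All randomness flows from explicit seeds; re-running any stage with the
  same config is byte-identical, and every output TSV carries the config
  hash in its header.

## A worked run

```{r, eval = FALSE}
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
loci <- clump_loci(fit$summary_stats, d$genotypes, p_thresh = fit$alpha)

v <- st$validation
validate_loci(loci, v$phenotypes, v$genotypes, v$covariates,
              fit$basis, fit$assoc)
```

At these conditions the causal variant is discovered essentially always
and its target region tops the enrichment ranking in the large majority
of replicates; the confirmatory validation succeeds in most but not all
replicates, because with 20 components over 128 voxels the causal effect
direction sits close to the noise-eigenvalue bulk and the discovery PCs
capture it with varying fidelity. `scripts/acceptance.R` recomputes these
rates (together with the closed-form oracles) from scratch at every run —
the vignette deliberately quotes no number that script and the test suite
do not themselves compute.

## Known limitations

* The global–local combination is one reading of an under-specified
  construction (see above) and is swappable in one place.
* LDSC here is the unweighted regression with jackknife SEs, suitable for
  the simulated expectation model, not a drop-in for the reference
  implementation on real summary statistics.
* Enrichment nulls are unmatched on allele frequency.
* Fixed-effects validation only; no kinship/mixed models.
* The generator's LD is block-AR(1), not reference-panel LD, so LD-block
  analytics see cleaner block boundaries than real genomes provide.
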