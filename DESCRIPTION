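Package: cpcgwas
Title: Multivariate GWAS of Voxelwise Brain Phenotypes via Combined
    Principal Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and validation of genetic loci associated with
    high-dimensional voxelwise brain phenotypes. Summarizes whole-brain
    tissue-composition volumes (restricted isotropic N0, restricted
    directional ND, and free-water NF fractions) into principal
    components, combines per-component Wald statistics into a
    closed-form chi-squared omnibus test (with global-local Fisher
    variants), defines loci by LD and positional clumping, validates
    lead variants with confirmatory polyvoxel scores in independent
    samples, localizes signals with probability-weighted regional
    enrichment against a bootstrap null, and provides genome-wide
    summaries (eigenvalue-weighted average heritability from LD-score
    regression, rescaled multivariate chi-squared statistics, and
    LD-block signal overlap). Includes a synthetic-data generator with
    block-LD genotypes and spatially structured voxel phenotypes so the
    whole pipeline is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
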