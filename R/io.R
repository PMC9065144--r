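## Readers/writers for the field's formats (VCF, PLINK-style TSV triplets,
## NIfTI volumes, summary-statistics TSV) and the discovery/validation
## orchestrators with config hashing and manifests.

hash_config <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

write_tsv_hashed <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_hashed <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write genotypes as a plain-text VCF (GT field)
#'
#' @param G A `genotype_matrix`.
#' @param path Output file path (uncompressed `.vcf`).
#' @return The path, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  n <- nrow(G$dosages)
  gt <- matrix(c("0/0", "0/1", "1/1", "./.")[
    ifelse(is.na(t(G$dosages)), 4L, t(G$dosages) + 1L)],
    ncol(G$dosages), n)
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sprintf("S%04d", seq_len(n))),
                 collapse = "\t"))
  body <- cbind(G$chr, G$pos, G$snp, "A", "G", ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(body, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from VCF into a `genotype_matrix`
#'
#' Parses GT fields (alt-allele dosage; `./.` becomes missing) via vcfR.
#'
#' @param path Path to a VCF file.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop2("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")   # variants x samples
  dos_vs <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dos_vs[] <- known[gt]
  dosages <- t(dos_vs)                         # subjects x variants
  fix <- vcfR::getFIX(v)
  af <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(
    dosages = dosages,
    snp = unname(fix[, "ID"]),
    chr = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    maf = pmin(af, 1 - af),
    block = NULL
  ), class = "genotype_matrix")
}

#' Write genotypes as a PLINK-style TSV triplet
#'
#' Writes `<prefix>.variants.tsv` (snp, chr, pos, maf, block),
#' `<prefix>.samples.tsv`, and `<prefix>.dosages.tsv` (subject x SNP,
#' `NA` for missing).
#'
#' @param G A `genotype_matrix`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_genotypes_tsv <- function(G, prefix) {
  write_tsv_hashed(data.frame(snp = G$snp, chr = G$chr, pos = G$pos,
                              maf = G$maf %||% NA_real_,
                              block = G$block %||% NA_integer_),
                   paste0(prefix, ".variants.tsv"))
  write_tsv_hashed(data.frame(sample = sprintf("S%04d",
                                               seq_len(nrow(G$dosages)))),
                   paste0(prefix, ".samples.tsv"))
  dos <- as.data.frame(G$dosages)
  names(dos) <- G$snp
  write_tsv_hashed(dos, paste0(prefix, ".dosages.tsv"))
  invisible(prefix)
}

#' Read a PLINK-style genotype TSV triplet
#'
#' @param prefix Path prefix used by [write_genotypes_tsv()].
#' @return A `genotype_matrix`.
#' @export
read_genotypes_tsv <- function(prefix) {
  var <- read_tsv_hashed(paste0(prefix, ".variants.tsv"))
  dos <- as.matrix(read_tsv_hashed(paste0(prefix, ".dosages.tsv")))
  dimnames(dos) <- NULL
  storage.mode(dos) <- "integer"
  structure(list(dosages = dos, snp = var$snp, chr = as.character(var$chr),
                 pos = as.integer(var$pos), maf = var$maf,
                 block = var$block),
            class = "genotype_matrix")
}

#' Write a phenotype set as a 4-D NIfTI volume (subject as 4th axis)
#'
#' @param P A `phenotype_volumes` object.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_phenotypes_nifti <- function(P, path) {
  arr <- array(t(P$values), c(P$grid_dims, nrow(P$values)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a 4-D NIfTI phenotype volume (subject as 4th axis)
#'
#' @param path NIfTI file path.
#' @return A `phenotype_volumes` object.
#' @export
read_phenotypes_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  structure(list(values = t(matrix(arr, prod(d[1:3]), d[4])),
                 grid_dims = as.integer(d[1:3]),
                 mask = rep(TRUE, prod(d[1:3]))),
            class = "phenotype_volumes")
}

#' Write a region atlas as a 4-D NIfTI probability volume plus name table
#'
#' @param atlas A `region_atlas`.
#' @param path NIfTI path; region names go to `<path>.regions.tsv`.
#' @return The path, invisibly.
#' @export
write_atlas_nifti <- function(atlas, path) {
  arr <- array(atlas$P, c(atlas$grid_dims, ncol(atlas$P)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  write_tsv_hashed(data.frame(region = atlas$names),
                   paste0(path, ".regions.tsv"))
  invisible(path)
}

#' Read a region atlas written by [write_atlas_nifti()]
#'
#' @param path NIfTI path.
#' @return A `region_atlas`.
#' @export
read_atlas_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  nm <- read_tsv_hashed(paste0(path, ".regions.tsv"))$region
  structure(list(P = matrix(arr, prod(d[1:3]), d[4]), names = nm,
                 grid_dims = as.integer(d[1:3])),
            class = "region_atlas")
}

#' Assemble a run configuration for the orchestrators
#'
#' @param out_dir Output directory.
#' @param K Number of principal components.
#' @param cut_points Global-local cut points.
#' @param alpha Significance threshold (`NULL` for the [cpc_alpha()]
#'   default).
#' @param n_features Feature multiplicity for the default threshold.
#' @param p_thresh,r2_thresh,window_bp Clumping parameters.
#' @param maf_min,hwe_p_min,miss_max Variant QC thresholds.
#' @param bootstrap_B Enrichment bootstrap draws.
#' @param seed Master seed.
#' @param feature Feature label.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, K = 20, cut_points = c(5, 10),
                       alpha = NULL, n_features = 3,
                       p_thresh = NULL, r2_thresh = 0.1,
                       window_bp = 250000, maf_min = 0.005,
                       hwe_p_min = 1e-10, miss_max = 0.05,
                       bootstrap_B = 1000, seed = 1L,
                       feature = "pheno") {
  structure(list(out_dir = out_dir, K = K, cut_points = cut_points,
                 alpha = alpha, n_features = n_features,
                 p_thresh = p_thresh, r2_thresh = r2_thresh,
                 window_bp = window_bp, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, miss_max = miss_max,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed),
                 feature = feature),
            class = "run_config")
}

write_manifest <- function(dir, cfg_hash, stages, warnings = character(0)) {
  files <- list.files(dir, full.names = TRUE, recursive = TRUE)
  files <- files[basename(files) != "manifest.yaml"]
  manifest <- list(
    config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("cpcgwas")),
    stages = stages,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    warnings = as.list(warnings)
  )
  writeLines(yaml::as.yaml(manifest), file.path(dir, "manifest.yaml"))
  manifest
}

#' Run the discovery stage end to end
#'
#' QC filters -> PCA -> per-PC association -> CPC combination -> clumping.
#' Writes `summary_stats.tsv`, `loci.tsv`, `lead_betas.tsv` (per-PC
#' discovery coefficients of significant SNPs, needed for validation),
#' the PC basis (`eigenvalues.tsv`, `center.tsv`, `eigenvectors.nii.gz`),
#' `config.yaml`, and `manifest.yaml` with per-stage timings and file
#' checksums. Re-running with the same config and data reproduces
#' identical outputs.
#'
#' @param cfg A [run_config()].
#' @param genotypes A `genotype_matrix`.
#' @param phenotypes A `phenotype_volumes`.
#' @param covariates Covariate data.frame or `NULL`.
#' @return List with `fit` (the `cpc_gwas` object), `qc`, `loci`,
#'   `manifest`, invisibly.
#' @export
run_discovery <- function(cfg, genotypes, phenotypes, covariates = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- hash_config(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  writeLines(yaml::as.yaml(unclass(cfg)), file.path(cfg$out_dir, "config.yaml"))
  stages <- list()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  qc <- variant_filters(genotypes, cfg$maf_min, cfg$hwe_p_min, cfg$miss_max)
  Gk <- subset_snps(genotypes, which(qc$kept))
  stages$qc <- list(seconds = tic() - t0, n_kept = sum(qc$kept))

  t0 <- tic()
  fit <- cpc_gwas(phenotypes, Gk, covariates, K = cfg$K,
                  cut_points = cfg$cut_points, alpha = cfg$alpha,
                  n_features = cfg$n_features, feature = cfg$feature)
  stages$gwas <- list(seconds = tic() - t0,
                      n_significant = sum(fit$result$significant))

  t0 <- tic()
  p_thresh <- cfg$p_thresh %||% fit$alpha
  loci <- clump_loci(fit$summary_stats, Gk, p_thresh = p_thresh,
                     r2_thresh = cfg$r2_thresh, window_bp = cfg$window_bp)
  stages$clump <- list(seconds = tic() - t0, n_loci = nrow(loci))

  write_tsv_hashed(qc, file.path(cfg$out_dir, "variant_qc.tsv"), cfg_hash)
  write_tsv_hashed(fit$summary_stats,
                   file.path(cfg$out_dir, "summary_stats.tsv"), cfg_hash)
  write_tsv_hashed(loci, file.path(cfg$out_dir, "loci.tsv"), cfg_hash)
  sig_idx <- which(fit$result$significant)
  lead_betas <- cbind(data.frame(snp = fit$assoc$snp[sig_idx]),
                      as.data.frame(fit$assoc$beta[sig_idx, , drop = FALSE]))
  names(lead_betas)[-1] <- paste0("pc", seq_len(fit$K))
  write_tsv_hashed(lead_betas, file.path(cfg$out_dir, "lead_betas.tsv"),
                   cfg_hash)
  write_tsv_hashed(data.frame(pc = seq_len(fit$K),
                              eigenvalue = fit$basis$values,
                              cum_var = fit$basis$cum_var),
                   file.path(cfg$out_dir, "eigenvalues.tsv"), cfg_hash)
  write_tsv_hashed(data.frame(voxel = seq_along(fit$basis$center),
                              mean = fit$basis$center),
                   file.path(cfg$out_dir, "center.tsv"), cfg_hash)
  gd <- fit$basis$grid_dims %||% c(ncol(phenotypes_values(phenotypes)), 1L, 1L)
  RNifti::writeNifti(
    RNifti::asNifti(array(fit$basis$vectors, c(gd, fit$K))),
    file.path(cfg$out_dir, "eigenvectors.nii.gz"))

  manifest <- write_manifest(cfg$out_dir, cfg_hash, stages)
  invisible(list(fit = fit, qc = qc, loci = loci, manifest = manifest))
}

phenotypes_values <- function(P) {
  if (inherits(P, "phenotype_volumes")) P$values else as.matrix(P)
}

#' Subset a genotype matrix to selected SNP columns
#'
#' @param G A `genotype_matrix`.
#' @param idx Integer column indices to keep.
#' @return A `genotype_matrix` restricted to `idx`.
#' @export
subset_snps <- function(G, idx) {
  structure(list(dosages = G$dosages[, idx, drop = FALSE],
                 snp = G$snp[idx], chr = G$chr[idx], pos = G$pos[idx],
                 maf = G$maf[idx], block = G$block[idx]),
            class = "genotype_matrix")
}

#' Run the validation stage against discovery artifacts
#'
#' Reads the discovery loci and per-PC coefficients from `discovery_dir`,
#' builds each lead SNP's polyvoxel score in the validation sample using
#' the in-memory discovery basis, runs the confirmatory tests with a
#' Bonferroni threshold of 0.05 over the number of discovered loci, and
#' writes `validation.tsv` plus a manifest. Warns when the validation
#' subjects appear to be the discovery subjects (non-independence).
#'
#' @param cfg A [run_config()] (its `out_dir` receives the report).
#' @param discovery_dir Directory written by [run_discovery()].
#' @param fit The discovery `cpc_gwas` object (carries the basis; the
#'   eigenvector archive in `discovery_dir` is for external reuse).
#' @param genotypes,phenotypes,covariates Validation-sample data.
#' @return List with `report` (validation data.frame) and `manifest`,
#'   invisibly.
#' @export
run_validation <- function(cfg, discovery_dir, fit, genotypes, phenotypes,
                           covariates = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  loci_path <- file.path(discovery_dir, "loci.tsv")
  if (!file.exists(loci_path)) stop2("missing discovery artifact: ", loci_path)
  loci <- read_tsv_hashed(loci_path)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- hash_config(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  warns <- character(0)
  if (nrow(genotypes$dosages) == fit$n_subjects &&
      isTRUE(all.equal(genotypes$dosages,
                       fit$assoc_dosages %||% genotypes$dosages)) &&
      identical(dim(phenotypes_values(phenotypes)),
                c(fit$n_subjects, nrow(fit$basis$vectors))) &&
      isTRUE(all.equal(colMeans(phenotypes_values(phenotypes)),
                       fit$basis$center, tolerance = 1e-12))) {
    warns <- "validation sample appears identical to the discovery sample"
    warning(warns)
  }
  t0 <- proc.time()[["elapsed"]]
  report <- validate_loci(loci, phenotypes, genotypes, covariates,
                          fit$basis, fit$assoc)
  stages <- list(validate = list(seconds = proc.time()[["elapsed"]] - t0,
                                 n_loci = nrow(report),
                                 n_validated = sum(report$validated %in% TRUE)))
  write_tsv_hashed(report, file.path(cfg$out_dir, "validation.tsv"), cfg_hash)
  manifest <- write_manifest(cfg$out_dir, cfg_hash, stages, warns)
  invisible(list(report = report, manifest = manifest))
}
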