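#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end synthetic analysis in one
#' validated list: the cohort design, the generating variance profiles,
#' the peptide filter thresholds (presence >= 0.90 to pass outright,
#' presence > 1/3 for candidacy, residual fraction < 0.65, top-3
#' summarisation), the variance-model options and the pQTL options (10
#' principal components, 1-kb cis window, 20,000 permutations, 10% FDR).
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param design A [cohort_design()] (defaults to the 36 MZ + 22 DZ,
#'   two-visit design).
#' @param profiles A `variance_profile` table (defaults to
#'   [reference_variance_profiles()]).
#' @param n_peptides Peptides per protein for the synthetic evidence layer.
#' @param presence_high,presence_low,residual_max,top_k Quantification
#'   filter thresholds.
#' @param reml,n_starts,ci_level Variance-model options.
#' @param pqtl Logical: run the pQTL stage.
#' @param k_pcs,window,n_perm,fdr pQTL options.
#' @param pqtl_pve Optional named numeric: per-gene variance fractions to
#'   inject as true SNP effects.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, design = cohort_design(seed = seed),
                       profiles = reference_variance_profiles(),
                       n_peptides = 4,
                       presence_high = 0.90, presence_low = 1 / 3,
                       residual_max = 0.65, top_k = 3,
                       reml = FALSE, n_starts = 5, ci_level = 0.95,
                       pqtl = TRUE, k_pcs = 10, window = 1000,
                       n_perm = 20000, fdr = 0.10, pqtl_pve = NULL) {
  stopifnot(presence_high > presence_low, presence_high <= 1,
            residual_max > 0, residual_max <= 1, top_k >= 1,
            ci_level > 0, ci_level < 1, window > 0, fdr > 0, fdr < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the [run_config()] defaults; the
#' `design` block is passed to [cohort_design()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$design)) args$design <- do.call(cohort_design, y$design)
  for (k in setdiff(names(y), "design")) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

#' Run the full synthetic twin-proteomics pipeline
#'
#' Executes simulate -> quantify -> decompose -> (optionally) pQTL scan,
#' writing per-stage TSVs, a JSON summary and a log into `out_dir`.
#' Re-running with the same configuration reproduces every output
#' byte-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `filter_report`, `proteins`, `fits`, `pqtl`, `summary`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  seed_tag <- sprintf("seed=%d", config$seed)
  logf("stage=simulate %s", seed_tag)

  cohort <- simulate_cohort(config$design)
  prof <- config$profiles
  proteins_true <- simulate_protein_levels(cohort, prof,
                                           seed = derive_seed(config$seed,
                                                              "proteins"))
  snps <- simulate_cis_snps(prof$protein,
                            seed = derive_seed(config$seed, "snps"))
  genotypes <- simulate_genotypes(cohort, snps$specs,
                                  seed = derive_seed(config$seed, "geno"))
  if (!is.null(config$pqtl_pve)) {
    for (gn in names(config$pqtl_pve)) {
      sp <- snps$specs[snps$specs$gene == gn, ][1, ]
      sp$pve <- config$pqtl_pve[[gn]]
      proteins_true <- inject_pqtl_effect(proteins_true, genotypes, sp,
                                          cohort)
    }
  }
  pmap <- peptide_map(prof$protein, n_peptides = config$n_peptides,
                      seed = derive_seed(config$seed, "map"))
  peptides <- simulate_peptides(proteins_true, pmap,
                                seed = derive_seed(config$seed, "pep"))
  write_cohort_tsv(cohort, file.path(out_dir, "cohort.tsv"),
                   comments = seed_tag)
  write_matrix_tsv(peptides$values, file.path(out_dir, "peptides.tsv"),
                   comments = c(seed_tag, "stage=simulate"),
                   mask = peptides$missing)
  write_vcf(genotypes, snps$snp_ann, file.path(out_dir, "genotypes.vcf"),
            comments = seed_tag)
  write_snp_bed(cbind(snps$snp_ann, gene = snps$specs$gene),
                file.path(out_dir, "snps.tsv"))

  logf("stage=quantify peptides=%d", nrow(peptides$values))
  filt <- filter_peptides(peptides, cohort,
                          presence_high = config$presence_high,
                          presence_low = config$presence_low,
                          residual_max = config$residual_max,
                          seed = derive_seed(config$seed, "filter"))
  filled <- requantify_missing(filt$peptides,
                               seed = derive_seed(config$seed, "requant"))
  proteins <- summarize_protein(filled, top_k = config$top_k)
  utils::write.table(filt$report, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(proteins, file.path(out_dir, "proteins.tsv"),
                   comments = c(seed_tag, "stage=quantify"))

  logf("stage=decompose proteins=%d", nrow(proteins))
  fits <- decompose_proteins(proteins, cohort, reml = config$reml,
                             n_starts = config$n_starts)
  utils::write.table(fits, file.path(out_dir, "fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pq <- NULL
  if (isTRUE(config$pqtl)) {
    k <- min(config$k_pcs, nrow(proteins) - 1,
             sum(cohort$visit == 1) - 2)
    logf("stage=pqtl genes=%d k_pcs=%d perms=%d", nrow(proteins), k,
         config$n_perm)
    pq <- map_pqtls(proteins, cohort, genotypes, snps$snp_ann, snps$tss,
                    k_pcs = k, window = config$window, B = config$n_perm,
                    fdr = config$fdr,
                    seed = derive_seed(config$seed, "pqtl"), fits = fits)
    utils::write.table(pq, file.path(out_dir, "pqtl.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    n_samples = nrow(cohort),
    n_peptides_in = nrow(peptides$values),
    filter_counts = as.list(table(filt$report$class)),
    n_proteins = nrow(proteins),
    mean_proportions = as.list(colMeans(
      fits[, paste0("prop_", c("g", "c", "id", "w", "e"))])),
    n_significant_pqtl = if (is.null(pq)) NA else sum(pq$significant)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  logf("stage=done")
  invisible(list(cohort = cohort, filter_report = filt$report,
                 proteins = proteins, fits = fits, pqtl = pq,
                 summary = summary))
}
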