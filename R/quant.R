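#' Two-step peptide consistency filter
#'
#' Classifies every peptide of a peptide matrix for protein quantification:
#' non-proteotypic peptides (shared between proteins) are discarded first;
#' peptides identified in at least 90% of samples pass unconditionally
#' (`step1`); peptides identified in more than 1/3 but less than 90% of
#' samples are kept only when, after noise-floor re-quantification, the
#' residual (unexplained) variance fraction of a peptide-level twin-model
#' fit is below 65% (`step2`); everything else is dropped.  The report is
#' exhaustive: each input peptide lands in exactly one class.
#'
#' @param peptides A `peptide_matrix` (see [simulate_peptides()]) or a list
#'   with `values`, `missing` and `mapping`.
#' @param cohort The `twin_cohort` the columns belong to; `NULL` disables
#'   the step-2 model fits (those candidates are dropped with a warning).
#' @param presence_high,presence_low,residual_max The three thresholds:
#'   presence >= `presence_high` (0.90, inclusive) for step 1, presence
#'   strictly above `presence_low` (1/3) for step-2 candidacy, residual
#'   fraction < `residual_max` (0.65) to survive step 2.
#' @param fit_fn Function `(y, cohort) -> residual variance fraction` used
#'   for the step-2 criterion; the default rank-normalises the
#'   re-quantified peptide values and fits the longitudinal twin model.
#' @param seed Seed for the re-quantification jitter inside step 2.
#' @return List with `report` (data.frame: `peptide`, `protein`,
#'   `presence`, `proteotypic`, `residual_fraction`, `class` in
#'   `step1`/`step2`/`dropped`) and `peptides`, the filtered
#'   `peptide_matrix`.
#' @export
filter_peptides <- function(peptides, cohort = NULL,
                            presence_high = 0.90, presence_low = 1 / 3,
                            residual_max = 0.65, fit_fn = NULL,
                            seed = 29L) {
  vals <- peptides$values
  miss <- peptides$missing
  map <- peptides$mapping
  stopifnot(all(rownames(vals) == map$peptide))
  presence <- rowMeans(!miss)
  cls <- rep("dropped", nrow(vals))
  resid_frac <- rep(NA_real_, nrow(vals))
  cls[map$proteotypic & presence >= presence_high] <- "step1"
  cand <- which(map$proteotypic & presence > presence_low &
                  presence < presence_high)
  if (length(cand) > 0) {
    if (is.null(fit_fn) && is.null(cohort)) {
      warning("no cohort metadata: step-2 candidates dropped")
    } else {
      if (is.null(fit_fn)) {
        filled <- requantify_missing(peptides, seed = seed)
        fit_fn <- function(i) {
          y <- rank_normal(filled$values[i, ])
          fit <- fit_twin_model(y, cohort, n_starts = 3)
          unname(fit$proportions["e"])
        }
        resid_frac[cand] <- vapply(cand, fit_fn, numeric(1))
      } else {
        resid_frac[cand] <- vapply(cand, function(i)
          fit_fn(vals[i, ], cohort), numeric(1))
      }
      cls[cand[resid_frac[cand] < residual_max]] <- "step2"
    }
  }
  keep <- cls != "dropped"
  out <- peptides
  out$values <- vals[keep, , drop = FALSE]
  out$missing <- miss[keep, , drop = FALSE]
  out$mapping <- map[keep, , drop = FALSE]
  if (!is.null(out$truth)) out$truth <- out$truth[keep, , drop = FALSE]
  list(
    report = data.frame(peptide = map$peptide, protein = map$protein,
                        presence = presence, proteotypic = map$proteotypic,
                        residual_fraction = resid_frac, class = cls,
                        stringsAsFactors = FALSE),
    peptides = out
  )
}

#' Re-quantify missing peptide cells at the sample noise floor
#'
#' Replaces each missing cell with its sample's noise floor -- by default
#' the 5th percentile of that sample's observed log-intensities -- plus a
#' small Gaussian jitter, mimicking re-quantification of undetected
#' peptides at the local background signal level.  Observed cells are
#' untouched and imputed cells stay flagged in the mask.
#'
#' @param peptides A `peptide_matrix`.
#' @param floor_quantile Per-sample quantile used as the noise floor.
#' @param jitter_sd SD of the jitter added to imputed values (log10).
#' @param seed Integer seed for the jitter.
#' @return The completed `peptide_matrix` (no NA cells; `missing` still
#'   marks which cells were imputed).
#' @export
requantify_missing <- function(peptides, floor_quantile = 0.05,
                               jitter_sd = 0.1, seed = 31L) {
  vals <- peptides$values
  miss <- peptides$missing
  if (!any(miss)) return(peptides)
  n_obs <- colSums(!miss)
  if (any(n_obs == 0))
    stop("sample(s) with zero observed values: ",
         paste(colnames(vals)[n_obs == 0], collapse = ", "))
  floors <- vapply(seq_len(ncol(vals)), function(j)
    stats::quantile(vals[!miss[, j], j], floor_quantile, names = FALSE),
    numeric(1))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  idx <- which(miss, arr.ind = TRUE)
  vals[miss] <- floors[idx[, 2]] +
    stats::rnorm(nrow(idx), 0, jitter_sd)
  out <- peptides
  out$values <- vals
  out
}

#' Top-3 peptide-to-protein summarisation
#'
#' Protein abundance per sample is the sum, on the linear intensity scale,
#' of the protein's three most abundant peptides (all peptides when fewer
#' than three are available).  "Most abundant" is judged by the
#' cross-sample mean linear intensity, so the chosen peptide set is fixed
#' across samples.
#'
#' @param peptides A complete `peptide_matrix` (after
#'   [requantify_missing()]); values on the log10 scale.
#' @param top_k Number of peptides summed (default 3).
#' @return Numeric matrix, proteins x samples, log10 of the summed linear
#'   intensities.  Proteins with zero retained peptides are omitted with a
#'   warning.
#' @export
summarize_protein <- function(peptides, top_k = 3) {
  vals <- peptides$values
  if (anyNA(vals)) stop("missing cells present; re-quantify first")
  map <- peptides$mapping
  lin <- 10^vals
  prots <- unique(map$protein)
  out <- matrix(NA_real_, length(prots), ncol(vals),
                dimnames = list(prots, colnames(vals)))
  for (pr in prots) {
    i <- which(map$protein == pr)
    if (length(i) == 0) next
    mns <- rowMeans(lin[i, , drop = FALSE])
    sel <- i[order(mns, decreasing = TRUE)][seq_len(min(top_k, length(i)))]
    out[pr, ] <- log10(colSums(lin[sel, , drop = FALSE]))
  }
  out
}

#' Coefficient of variation of replicate measurements
#'
#' CV per protein is `sd/mean` of the linear-scale intensities across
#' replicate columns, in percent.  Proteins whose replicate mean is zero
#' get `NA`.
#'
#' @param replicates Numeric matrix, proteins x replicates, log10
#'   intensities (set `log = FALSE` for linear input).
#' @param log Whether the input is log10-scaled (default `TRUE`).
#' @return List with `cv` (per-protein CV, %), `median_cv` and
#'   `frac_below_25` (fraction of proteins with CV < 25%).
#' @export
compute_cv <- function(replicates, log = TRUE) {
  stopifnot(ncol(replicates) >= 2)
  lin <- if (log) 10^replicates else replicates
  m <- rowMeans(lin)
  s <- apply(lin, 1, stats::sd)
  cv <- ifelse(m == 0, NA_real_, 100 * s / m)
  list(cv = cv, median_cv = stats::median(cv, na.rm = TRUE),
       frac_below_25 = mean(cv < 25, na.rm = TRUE))
}

#' Per-protein variability statistics
#'
#' For each protein: the standard deviation of its log10 fold change from
#' its cohort-average level, the ratio between its extreme linear
#' intensities, and a flag for a more than tenfold extreme range.
#'
#' @param proteins Numeric matrix, proteins x samples, log10 intensities.
#' @return A data.frame with `protein`, `sd_log10_fc`, `extreme_ratio`,
#'   `over_10fold`, plus attributes `frac_over_10fold`.
#' @export
variability_stats <- function(proteins) {
  stopifnot(is.matrix(proteins), ncol(proteins) >= 2)
  if (any(!is.finite(proteins))) stop("non-finite intensities")
  fc <- proteins - rowMeans(proteins)   # log10 fold change from mean
  sdfc <- apply(fc, 1, stats::sd)
  ratio <- 10^(apply(proteins, 1, max) - apply(proteins, 1, min))
  out <- data.frame(protein = rownames(proteins), sd_log10_fc = sdfc,
                    extreme_ratio = ratio, over_10fold = ratio > 10,
                    stringsAsFactors = FALSE)
  attr(out, "frac_over_10fold") <- mean(out$over_10fold)
  out
}

#' Hierarchical clustering of samples with adjacent-relative count
#'
#' Clusters the samples of a complete peptide (or protein) matrix --
#' log-scale values are centred along both dimensions and row-normalised,
#' samples are compared by Pearson correlation distance, average linkage --
#' and counts the samples whose immediate dendrogram sibling is a leaf from
#' the same twin pair or the same individual's other visit.  An optional
#' label-permutation null gives the count expected by chance.
#'
#' @param values Complete numeric matrix, analytes x samples.
#' @param cohort `twin_cohort` matching the columns.
#' @param n_perm Number of label permutations for the null (0 to skip).
#' @param seed Seed for the permutations.
#' @return List with `hclust`, `n_adjacent` (samples adjacent to a
#'   relative), `frac_adjacent`, and when `n_perm > 0`, `null_frac`
#'   (numeric vector of permuted fractions).
#' @export
cluster_samples <- function(values, cohort, n_perm = 0, seed = 37L) {
  if (anyNA(values)) stop("missing cells present; re-quantify first")
  stopifnot(ncol(values) == nrow(cohort))
  x <- values - rowMeans(values)
  x <- sweep(x, 2, colMeans(x))
  rsd <- apply(x, 1, stats::sd)
  x <- x[rsd > 0, , drop = FALSE] / rsd[rsd > 0]
  dd <- stats::as.dist(1 - stats::cor(x))
  hc <- stats::hclust(dd, method = "average")

  # leaves merged together at a first-level node are dendrogram siblings
  sib_pairs <- which(hc$merge[, 1] < 0 & hc$merge[, 2] < 0)
  related <- function(i, j)
    cohort$pair_id[i] == cohort$pair_id[j]   # co-twin or same individual
  count_adjacent <- function(ord) {
    n <- 0L
    for (m in sib_pairs) {
      i <- ord[-hc$merge[m, 1]]; j <- ord[-hc$merge[m, 2]]
      if (related(i, j)) n <- n + 2L
    }
    n
  }
  n_adj <- count_adjacent(seq_len(nrow(cohort)))
  out <- list(hclust = hc, n_adjacent = n_adj,
              frac_adjacent = n_adj / nrow(cohort))
  if (n_perm > 0) {
    rng <- local_rng(seed)
    on.exit(rng$restore())
    out$null_frac <- vapply(seq_len(n_perm), function(b)
      count_adjacent(sample(nrow(cohort))) / nrow(cohort), numeric(1))
  }
  out
}
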