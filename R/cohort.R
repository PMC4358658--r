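#' Describe a longitudinal twin cohort design
#'
#' A design captures the sampling frame of a classical longitudinal twin
#' study: a number of monozygotic (MZ) and dizygotic (DZ) same-sex pairs,
#' each individual sampled at `n_visits` clinic visits, with both members of
#' a pair attending each visit together.  The default interval between the
#' two visits (5.2 +/- 1.4 years) matches a typical mid-life plasma
#' profiling cohort.
#'
#' @param n_mz_pairs,n_dz_pairs Number of MZ and DZ twin pairs (at least one
#'   pair in total, each count >= 0; the default cohort has 36 MZ and 22 DZ
#'   pairs, i.e. 116 individuals).
#' @param n_visits Number of visits per individual (default 2).
#' @param interval_mean_years,interval_sd_years Mean and standard deviation
#'   (years) of the normally distributed between-visit interval, truncated
#'   below at `min_interval_years`.
#' @param min_interval_years Lower truncation for drawn intervals (years).
#' @param n_plates Number of sample-preparation plates over which samples
#'   are randomised.
#' @param seed Integer seed making the cohort draw reproducible.
#'
#' @return An object of class `cohort_design` (a list of the validated
#'   fields).
#' @seealso [simulate_cohort()]
#' @export
cohort_design <- function(n_mz_pairs = 36, n_dz_pairs = 22, n_visits = 2,
                          interval_mean_years = 5.2, interval_sd_years = 1.4,
                          min_interval_years = 0.5, n_plates = 3, seed = 1L) {
  stopifnot(length(n_mz_pairs) == 1, length(n_dz_pairs) == 1,
            n_mz_pairs >= 0, n_dz_pairs >= 0,
            n_visits >= 1, n_plates >= 1,
            interval_sd_years >= 0, min_interval_years > 0)
  if (n_mz_pairs + n_dz_pairs < 1)
    stop("the design must contain at least one twin pair")
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs),
    n_dz_pairs = as.integer(n_dz_pairs),
    n_visits = as.integer(n_visits),
    interval_mean_years = interval_mean_years,
    interval_sd_years = interval_sd_years,
    min_interval_years = min_interval_years,
    n_plates = as.integer(n_plates),
    seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Simulate a longitudinal twin cohort frame
#'
#' Draws the sampling metadata for every plasma sample of the design: pair
#' and individual identifiers, zygosity, visit index, the time covariate
#' (0 at visit 1 and the realised inter-visit interval, in years, at later
#' visits -- the same for both sisters of a pair, who attend together), and
#' a balanced random plate assignment.
#'
#' @param design A [cohort_design()].
#' @return A `data.frame` of class `twin_cohort` with one row per sample and
#'   columns `sample_id`, `individual_id`, `pair_id`, `zygosity`
#'   (`"MZ"`/`"DZ"`), `twin` (1 or 2 within the pair), `visit`, `time`
#'   (years since visit 1) and `plate` (factor).
#' @examples
#' coh <- simulate_cohort(cohort_design(n_mz_pairs = 2, n_dz_pairs = 1))
#' table(coh$zygosity, coh$visit)
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n_pairs <- design$n_mz_pairs + design$n_dz_pairs
  rng <- local_rng(design$seed)
  zyg_pair <- rep(c("MZ", "DZ"), c(design$n_mz_pairs, design$n_dz_pairs))
  pair_id <- sprintf("F%03d", seq_len(n_pairs))

  # inter-visit gaps per pair (shared by the two sisters), truncated normal
  gaps <- matrix(0, n_pairs, design$n_visits)
  if (design$n_visits > 1) {
    for (v in 2:design$n_visits) {
      g <- stats::rnorm(n_pairs, design$interval_mean_years,
                        design$interval_sd_years)
      g <- pmax(g, design$min_interval_years)
      gaps[, v] <- gaps[, v - 1] + g
    }
  }

  rows <- expand.grid(visit = seq_len(design$n_visits), twin = 1:2,
                      pair = seq_len(n_pairs), KEEP.OUT.ATTRS = FALSE)
  # order: pair, twin, visit so family blocks are contiguous
  rows <- rows[order(rows$pair, rows$twin, rows$visit), , drop = FALSE]
  out <- data.frame(
    sample_id = sprintf("%s.%d.V%d", pair_id[rows$pair], rows$twin, rows$visit),
    individual_id = sprintf("%s.%d", pair_id[rows$pair], rows$twin),
    pair_id = pair_id[rows$pair],
    zygosity = zyg_pair[rows$pair],
    twin = rows$twin,
    visit = rows$visit,
    time = gaps[cbind(rows$pair, rows$visit)],
    stringsAsFactors = FALSE
  )
  plate <- sample(rep_len(seq_len(design$n_plates), nrow(out)))
  out$plate <- factor(sprintf("plate%d", plate),
                      levels = sprintf("plate%d", seq_len(design$n_plates)))
  rownames(out) <- out$sample_id
  rng$restore()
  attr(out, "design") <- design
  class(out) <- c("twin_cohort", "data.frame")
  out
}

#' @export
print.twin_cohort <- function(x, ...) {
  np <- length(unique(x$pair_id))
  cat(sprintf("twin cohort: %d samples, %d individuals, %d pairs (%d MZ / %d DZ), %d visit(s)\n",
              nrow(x), length(unique(x$individual_id)), np,
              length(unique(x$pair_id[x$zygosity == "MZ"])),
              length(unique(x$pair_id[x$zygosity == "DZ"])),
              max(x$visit)))
  NextMethod()
  invisible(x)
}

# Restrict a cohort to one visit (one sample per individual).
#' Subset a cohort to a single visit
#'
#' @param cohort A `twin_cohort`.
#' @param visit Visit index to keep.
#' @return The restricted `twin_cohort`.
#' @export
cohort_visit <- function(cohort, visit) {
  stopifnot(visit %in% cohort$visit)
  out <- cohort[cohort$visit == visit, , drop = FALSE]
  class(out) <- class(cohort)
  out
}

# Scoped RNG helper: sets the seed, and restores the caller's RNG state when
# $restore() is called, so simulators do not disturb the global stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

# Deterministic small-integer sub-seed derived from a base seed and a label,
# kept below 2^31.  Used to give each analyte / gene its own stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) *
             (seq_along(utf8ToInt(as.character(label))) %% 31 + 1))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
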