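#' Define a protein variance profile
#'
#' A variance profile gives the five generating variance components of a
#' protein's log-intensity on the twin model's scale: additive genetic
#' (`g`), common environment shared by a pair (`c`), individual environment
#' stable across visits (`id`), longitudinal/visit effect shared by a pair
#' at one visit (`w`) and residual noise (`e`).  Proportions of the total
#' are the usual twin-study summaries (heritability is `g`'s share).
#'
#' @param protein Protein (or analyte) identifier.
#' @param g,c_,id,w,e Non-negative variance components (log-intensity
#'   units squared).  `c_` is the common-environment component (trailing
#'   underscore avoids masking [base::c()]).
#' @return A one-row `data.frame` of class `variance_profile` with columns
#'   `protein`, `g`, `c`, `id`, `w`, `e`.
#' @examples
#' variance_profile("APOA", g = 0.6633, c_ = 0.1845, e = 0.1521)
#' @export
variance_profile <- function(protein, g = 0, c_ = 0, id = 0, w = 0, e = 1) {
  v <- c(g = g, c = c_, id = id, w = w, e = e)
  if (any(v < 0)) stop("variance components must be non-negative")
  if (sum(v) <= 0) stop("total variance must be positive")
  out <- data.frame(protein = as.character(protein), g = g, c = c_,
                    id = id, w = w, e = e, stringsAsFactors = FALSE)
  class(out) <- c("variance_profile", "data.frame")
  out
}

#' Combine variance profiles into a profile table
#'
#' @param ... `variance_profile` rows (or data.frames with the same
#'   columns).
#' @return A `variance_profile` data.frame, one row per protein.
#' @export
variance_profiles <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  stopifnot(!anyDuplicated(out$protein))
  class(out) <- c("variance_profile", "data.frame")
  out
}

#' Reference variance profiles for well-characterised plasma proteins
#'
#' Published twin-study variance decompositions for plasma proteins that are
#' each dominated by one of the four biological components: apolipoprotein(a)
#' (LPA; strongly heritable), Ig alpha-2 chain C region (IGHA2; common
#' environment), cell division cycle 5-like protein (CDC5L; individual
#' environment) and beta-actin-like protein 2 (ACTBL2; longitudinal).  These
#' serve as realistic generating truths for simulation studies: each row's
#' components are proportions of a unit total variance.
#'
#' @return A `variance_profile` data.frame with rownames equal to the gene
#'   symbol and columns `protein`, `g`, `c`, `id`, `w`, `e`.
#' @examples
#' reference_variance_profiles()["LPA", ]
#' @export
reference_variance_profiles <- function() {
  out <- variance_profiles(
    variance_profile("LPA",    g = 0.6633, c_ = 0.1845, id = 0.0000, w = 0.0000, e = 0.1521),
    variance_profile("IGHA2",  g = 0.0194, c_ = 0.6688, id = 0.2222, w = 0.0082, e = 0.0813),
    variance_profile("CDC5L",  g = 0.0682, c_ = 0.0000, id = 0.5295, w = 0.1457, e = 0.2566),
    variance_profile("ACTBL2", g = 0.0000, c_ = 0.0000, id = 0.0000, w = 0.5354, e = 0.4646),
    variance_profile("F12",    g = 0.0000, c_ = 0.5862, id = 0.1755, w = 0.0764, e = 0.1619),
    variance_profile("NES",    g = 0.0000, c_ = 0.0000, id = 0.0938, w = 0.4692, e = 0.4371),
    variance_profile("CD5L",   g = 0.6180, c_ = 0.0409, id = 0.1877, w = 0.0000, e = 0.1534),
    variance_profile("APOH",   g = 0.0000, c_ = 0.1009, id = 0.3807, w = 0.1324, e = 0.3861)
  )
  rownames(out) <- out$protein
  out
}

as_profile_matrix <- function(profiles) {
  stopifnot(all(c("protein", "g", "c", "id", "w", "e") %in% names(profiles)))
  m <- as.matrix(profiles[, c("g", "c", "id", "w", "e")])
  rownames(m) <- profiles$protein
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("variance components must be non-negative")
  m
}
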