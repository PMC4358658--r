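# Build a peptide_matrix by hand (values + mask + mapping) without the
# simulator, for exact-control filter tests.
manual_peptides <- function(values, missing, protein, proteotypic = TRUE) {
  mapping <- data.frame(peptide = rownames(values), protein = protein,
                        offset = 0,
                        proteotypic = rep_len(proteotypic, nrow(values)),
                        stringsAsFactors = FALSE)
  attr(mapping, "noise_sd") <- 0
  class(mapping) <- c("peptide_map", "data.frame")
  vals <- values
  vals[missing] <- NA_real_
  structure(list(values = vals, missing = missing, truth = values,
                 mapping = mapping), class = "peptide_matrix")
}

test_that("presence thresholds are inclusive at 90% and exclusive at 1/3", {
  vals <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  miss <- matrix(FALSE, 4, 10, dimnames = dimnames(vals))
  miss[1, 1] <- TRUE          # 9/10 present -> step1 (boundary, kept)
  miss[2, 1:7] <- TRUE        # 3/10 present -> dropped (below 1/3)
  miss[4, 1:2] <- TRUE        # 8/10 present, non-proteotypic -> dropped
  pep <- manual_peptides(vals, miss, protein = c("A", "A", "B", "B"),
                         proteotypic = c(TRUE, TRUE, TRUE, FALSE))
  out <- suppressWarnings(filter_peptides(pep, cohort = NULL))
  expect_equal(out$report$class, c("step1", "dropped", "step1", "dropped"))
  # the partition is exhaustive and exclusive
  expect_true(all(out$report$class %in% c("step1", "step2", "dropped")))
  expect_equal(nrow(out$report), 4)
})

test_that("step-2 candidates are kept iff their residual fraction < 65%", {
  coh <- simulate_cohort(cohort_design(30, 20, seed = 151))
  n <- nrow(coh)
  prof <- variance_profiles(
    variance_profile("STRUCT", g = .6, c_ = .2, id = .1, w = .05, e = .05),
    variance_profile("NOISE", e = 1))
  Y <- simulate_protein_levels(coh, prof, seed = 152)
  set.seed(153)
  # two always-present low-abundance peptides pin the noise floor; the two
  # candidates lose their lowest third of cells (abundance censoring)
  vals <- rbind(bg1 = -4 + rnorm(n, 0, 0.1), bg2 = -3.9 + rnorm(n, 0, 0.1),
                pepS = Y["STRUCT", ], pepN = Y["NOISE", ])
  colnames(vals) <- coh$sample_id
  miss <- matrix(FALSE, 4, n, dimnames = dimnames(vals))
  k <- floor(n / 3)
  miss["pepS", order(vals["pepS", ])[1:k]] <- TRUE
  miss["pepN", order(vals["pepN", ])[1:k]] <- TRUE
  pep <- manual_peptides(vals, miss,
                         protein = c("BG", "BG", "STRUCT", "NOISE"))
  out <- filter_peptides(pep, coh, seed = 154)
  rep <- out$report
  expect_equal(rep$class, c("step1", "step1", "step2", "dropped"))
  expect_lt(rep$residual_fraction[rep$peptide == "pepS"], 0.4)
  expect_gt(rep$residual_fraction[rep$peptide == "pepN"], 0.65)
  # without cohort metadata the candidates are dropped with a warning
  expect_warning(out2 <- filter_peptides(pep, cohort = NULL), "cohort")
  expect_equal(out2$report$class,
               c("step1", "step1", "dropped", "dropped"))
})

test_that("noise-floor re-quantification fills only the missing cells", {
  vals <- matrix(rnorm(200, 5), 10, 20,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:20)))
  miss <- matrix(FALSE, 10, 20, dimnames = dimnames(vals))
  pep_complete <- manual_peptides(vals, miss, protein = "A")
  expect_identical(requantify_missing(pep_complete), pep_complete)

  miss[3, 7] <- TRUE
  pep <- manual_peptides(vals, miss, protein = "A")
  out <- requantify_missing(pep, jitter_sd = 0.1, seed = 161)
  q <- quantile(vals[-3, 7], 0.05)   # observed 5th percentile of sample 7
  expect_lt(abs(out$values[3, 7] - q), 3 * 0.1)
  expect_equal(out$values[-3, ], pep$values[-3, ])    # observed untouched
  expect_true(out$missing[3, 7])                      # imputed cell flagged
  expect_false(anyNA(out$values))

  miss_all <- miss; miss_all[, 2] <- TRUE
  expect_error(requantify_missing(manual_peptides(vals, miss_all, "A")),
               "zero observed")
})

test_that("top-3 summarisation sums linear intensities of the fixed top set", {
  # 4 peptides with linear means 10, 5, 3, 1: protein = 18 on linear scale
  lin <- rbind(rep(10, 6), rep(5, 6), rep(3, 6), rep(1, 6))
  dimnames(lin) <- list(paste0("p", 1:4), paste0("s", 1:6))
  pep <- manual_peptides(log10(lin), matrix(FALSE, 4, 6, dimnames =
                                              dimnames(lin)), protein = "A")
  expect_equal(unname(10^summarize_protein(pep)[1, ]), rep(18, 6))
  # with only 2 peptides, both are summed
  pep2 <- manual_peptides(log10(lin[1:2, ]),
                          matrix(FALSE, 2, 6,
                                 dimnames = dimnames(lin[1:2, ])), "A")
  expect_equal(unname(10^summarize_protein(pep2)[1, ]), rep(15, 6))
  # selection uses cross-sample means: permuting samples keeps the set;
  # scaling all intensities by lambda scales the protein by lambda
  set.seed(162)
  vals <- matrix(rnorm(5 * 8, 3, 0.5), 5, 8,
                 dimnames = list(paste0("p", 1:5), paste0("s", 1:8)))
  pep3 <- manual_peptides(vals, matrix(FALSE, 5, 8, dimnames =
                                         dimnames(vals)), "A")
  perm <- sample(8)
  pep3p <- manual_peptides(vals[, perm], matrix(FALSE, 5, 8,
             dimnames = dimnames(vals[, perm])), "A")
  expect_equal(summarize_protein(pep3)[, perm], summarize_protein(pep3p)[, ])
  lam <- 2.5
  pep3s <- manual_peptides(vals + log10(lam), matrix(FALSE, 5, 8,
             dimnames = dimnames(vals)), "A")
  expect_equal(10^summarize_protein(pep3s), lam * 10^summarize_protein(pep3))
})

test_that("CV matches hand arithmetic and the lognormal closed form", {
  expect_equal(unname(compute_cv(rbind(log10(c(2, 2, 2))))$cv), 0)
  expect_equal(unname(compute_cv(rbind(log10(c(1, 3))))$cv),
               100 * sqrt(2) / 2, tolerance = 1e-8)
  # multiplicative noise sigma_log10 = 0.031 gives CV near 7.2%
  set.seed(171)
  reps <- matrix(rnorm(400 * 30, 4, 0.031), 400, 30)
  out <- compute_cv(reps)
  sig_ln <- 0.031 * log(10)
  expect_lt(abs(out$median_cv / 100 - sqrt(exp(sig_ln^2) - 1)), 0.005)
  expect_lt(abs(out$median_cv - 7.2), 1)
  expect_gt(out$frac_below_25, 0.99)
  # zero linear mean is reported as missing
  cvz <- compute_cv(rbind(c(1, -1), c(1, 2)), log = FALSE)
  expect_true(is.na(cvz$cv[1]))
})

test_that("variability statistics flag large extreme ranges", {
  m <- rbind(A = log10(c(2, 2, 2, 2)), B = log10(c(1, 4, 20, 100)))
  vs <- variability_stats(m)
  expect_equal(vs$sd_log10_fc[1], 0)
  expect_equal(vs$extreme_ratio[1], 1)
  expect_false(vs$over_10fold[1])
  expect_equal(vs$extreme_ratio[2], 100)
  expect_true(vs$over_10fold[2])
  expect_error(variability_stats(rbind(c(1, NA))), "non-finite")
  # SD of the log10 fold change recovers the generating spread
  set.seed(181)
  x <- matrix(rnorm(400, 5, 0.14), 1, 400,
              dimnames = list("A", paste0("s", 1:400)))
  expect_equal(variability_stats(x)$sd_log10_fc, 0.14, tolerance = 0.014)
})

test_that("clustering places duplicates and strong families adjacently", {
  coh <- small_cohort(8, 5, seed = 191)
  genes <- sprintf("P%02d", 1:30)
  # duplicated samples among noise are siblings at distance zero
  Y <- simulate_protein_levels(coh, flat_profiles(genes, g = 0, c_ = 0,
                                                  id = 0, w = 0, e = 1),
                               seed = 192)
  Y[, 2] <- Y[, 1] + rnorm(30, 0, 1e-4)
  hc <- cluster_samples(Y, coh)
  sib <- which(hc$hclust$merge[, 1] < 0 & hc$hclust$merge[, 2] < 0)
  leaves <- lapply(sib, function(m) -hc$hclust$merge[m, ])
  expect_true(any(vapply(leaves, function(l) setequal(l, c(1, 2)),
                         logical(1))))
  # high family variance: adjacency well above the permutation null
  Yfam <- simulate_protein_levels(coh, flat_profiles(genes, g = .5, c_ = .3,
                                                     id = .1, w = .05,
                                                     e = .05), seed = 193)
  out <- cluster_samples(Yfam, coh, n_perm = 100, seed = 194)
  expect_gt(out$frac_adjacent, quantile(out$null_frac, 0.99))
  # pure noise stays inside the null band
  Ynoise <- simulate_protein_levels(coh, flat_profiles(genes, g = 0, c_ = 0,
                                                       id = 0, w = 0, e = 1),
                                    seed = 195)
  out0 <- cluster_samples(Ynoise, coh, n_perm = 100, seed = 196)
  expect_lte(out0$frac_adjacent, quantile(out0$null_frac, 0.995))
  expect_error(cluster_samples(matrix(c(1, NA, 2, 3), 2), coh), "missing")
})
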