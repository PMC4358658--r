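test_that("rank_normal matches Blom normal quantiles and is rank-invariant", {
  # odd tie-free vector: the median maps to the exact centre
  v <- c(5, 1, 9, 3, 7)
  expect_equal(rank_normal(v)[v == 5], 0)
  # n = 2: +/- qnorm((2 - 3/8) / 2.25)
  expect_equal(rank_normal(c(1, 2)), qnorm(c(0.625 / 2.25, 1.625 / 2.25)))
  expect_equal(rank_normal(c(1, 2))[1], -0.5894558, tolerance = 1e-6)
  # invariance under monotone transformations
  x <- rexp(31)
  expect_equal(rank_normal(x), rank_normal(exp(x)))
  expect_equal(rank_normal(x), rank_normal(5 * x))
  # ties averaged, NA passed through, degenerate input rejected
  expect_equal(rank_normal(c(1, 1, 2))[1], rank_normal(c(1, 1, 2))[2])
  expect_true(is.na(rank_normal(c(1, NA, 2))[2]))
  expect_error(rank_normal(c(2, 2, 2)), "identical")
})

test_that("family covariance blocks have the printed structure", {
  comps <- c(g = 0.4, c = 0.2, id = 0.2, w = 0.1, e = 0.1)
  mz <- build_family_covariance("MZ", comps)
  dz <- build_family_covariance("DZ", comps)
  expect_equal(unname(diag(mz)), rep(1, 4))
  expect_equal(mz["twin1.v1", "twin2.v1"], 0.7)   # g + c + w
  expect_equal(dz["twin1.v1", "twin2.v1"], 0.5)   # g/2 + c + w
  expect_equal(mz["twin1.v1", "twin1.v2"], 0.8)   # g + c + id
  expect_equal(dz["twin1.v1", "twin1.v2"], 0.8)
  # kinship entries themselves: 1 for MZ, 1/2 for DZ co-twins
  kin_only <- c(g = 1, c = 0, id = 0, w = 0, e = 0)
  expect_equal(build_family_covariance("MZ", kin_only)["twin1.v1",
                                                       "twin2.v1"], 1.0)
  expect_equal(build_family_covariance("DZ", kin_only)["twin1.v1",
                                                       "twin2.v1"], 0.5)
  expect_equal(build_family_covariance("MZ", c(g = 0, c = 0, id = 0, w = 0,
                                               e = 1)), diag(4),
               ignore_attr = TRUE)
})

test_that("random non-negative components give PSD family blocks", {
  set.seed(71)
  for (i in 1:1000) {
    comps <- c(g = 0, c = 0, id = 0, w = 0, e = 0) + runif(5)
    z <- sample(c("MZ", "DZ"), 1)
    ev <- eigen(build_family_covariance(z, comps), only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
  }
})

test_that("block likelihood equals the dense MVN likelihood", {
  coh <- simulate_cohort(cohort_design(4, 2, seed = 81))
  y <- simulate_protein_levels(
    coh, variance_profile("P", .3, .2, .2, .1, .2), seed = 82)[1, ]
  set.seed(83)
  for (i in 1:4) {
    comps <- c(g = 0, c = 0, id = 0, w = 0, e = 0.05) + runif(5, 0, 0.5)
    expect_equal(as.numeric(twin_model_loglik(comps, y, coh)),
                 dense_mvn_loglik(comps, y, coh), tolerance = 1e-8)
  }
  # families with missing samples contribute their observed sub-block
  y2 <- y
  y2[c(2, 7, 11)] <- NA
  comps <- c(g = .25, c = .15, id = .2, w = .1, e = .3)
  expect_equal(as.numeric(twin_model_loglik(comps, y2, coh)),
               dense_mvn_loglik(comps, y2, coh), tolerance = 1e-8)
})

test_that("null data are attributed to the residual component", {
  coh <- simulate_cohort(cohort_design(1000, 1000, seed = 91))
  y <- rank_normal(simulate_protein_levels(
    coh, variance_profile("P", e = 1), seed = 92)[1, ])
  fit <- fit_twin_model(y, coh, n_starts = 3)
  expect_lt(fit$h2, 0.05)
  expect_gt(fit$proportions["e"], 0.9)
})

test_that("likelihood and estimates obey the symmetry contracts", {
  coh <- simulate_cohort(cohort_design(20, 12, seed = 101))
  y <- rank_normal(simulate_protein_levels(
    coh, variance_profile("P", .4, .1, .2, .1, .2), seed = 102)[1, ])
  fit <- fit_twin_model(y, coh)
  # sample reordering leaves the likelihood unchanged
  ord <- sample(length(y))
  coh2 <- coh[ord, ]
  class(coh2) <- class(coh)
  fit2 <- fit_twin_model(y[ord], coh2)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-5)
  # adding a constant is absorbed by the intercept
  fit3 <- suppressWarnings(fit_twin_model(y + 7, coh))
  expect_equal(fit3$components, fit$components, tolerance = 1e-3)
  # scaling equivariance: sigma^2 scale with lambda^2
  fit4 <- suppressWarnings(fit_twin_model(3 * y, coh))
  expect_equal(fit4$components, 9 * fit$components, tolerance = 0.02)
  # proportions always sum to one
  expect_equal(sum(fit$proportions), 1)
  expect_equal(sum(fit$stable_proportions), 1)
})

test_that("boundary LRT follows the chi-square mixture convention", {
  # closed-form checks of the 50:50 chi0/chi1 mixture
  coh <- simulate_cohort(cohort_design(15, 10, seed = 111))
  y <- rank_normal(simulate_protein_levels(
    coh, variance_profile("P", c_ = .4, e = .6), seed = 112)[1, ])
  fit <- fit_twin_model(y, coh, n_starts = 3)
  lt <- lrt_component(fit, "g")
  expect_gte(lt$lambda, 0)
  if (lt$lambda <= 1e-10) expect_equal(lt$p, 1)
  expect_equal(0.5 * pchisq(2.706, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  expect_equal(0.5 * pchisq(3.841, 1, lower.tail = FALSE), 0.025,
               tolerance = 1e-3)
})

test_that("boundary LRT holds its nominal level on null cohorts", {
  # truth has sigma2_g = 0 with the other components interior
  ps <- vapply(1:150, function(i) {
    coh <- simulate_cohort(cohort_design(200, 200, seed = 55000 + i))
    y <- rank_normal(simulate_protein_levels(
      coh, variance_profile("P", c_ = .3, id = .2, w = .1, e = .4),
      seed = 56000 + i)[1, ])
    fit <- fit_twin_model(y, coh, n_starts = 2)
    lrt_component(fit, "g")$p
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.005)
  expect_lte(mean(ps < 0.05), 0.09)
})

test_that("significance classification applies both rules", {
  fits <- data.frame(protein = c("A", "B", "C"),
                     prop_g = c(0.26, 0.10, 0.10),
                     p_g = c(0.5, 0.005, 0.05))
  out <- classify_significant(fits, components = "g")
  expect_setequal(out$g, c("A", "B"))
  expect_equal(unname(out$counts["g"]), 2L)
})

test_that("single-visit model recovers g and the merged pair component", {
  res <- t(vapply(1:100, function(i) {
    coh <- simulate_cohort(cohort_design(36, 22, seed = 7000 + i))
    y <- simulate_protein_levels(
      coh, variance_profile("P", g = .4, c_ = .2, w = .1, e = .3),
      seed = 8000 + i)[1, ]
    c1 <- cohort_visit(coh, 1)
    fit <- per_visit_fit(rank_normal(y[c1$sample_id]), c1)
    fit$proportions[c("g", "fam")]
  }, numeric(2)))
  # with one visit, c and w merge into the pair-shared component: 0.2 + 0.1
  expect_lt(abs(mean(res[, "g"]) - 0.4), 0.05)
  expect_lt(abs(mean(res[, "fam"]) - 0.3), 0.05)
  # two-visit input is rejected
  coh <- small_cohort()
  expect_error(per_visit_fit(rnorm(nrow(coh)), coh), "single visit")
})

test_that("single-visit fit on pure noise attributes nothing to g", {
  coh <- simulate_cohort(cohort_design(500, 500, seed = 121))
  c1 <- cohort_visit(coh, 1)
  y <- rank_normal(simulate_protein_levels(
    c1, variance_profile("P", e = 1), seed = 122)[1, ])
  fit <- per_visit_fit(y, c1)
  expect_lt(fit$proportions["g"], 0.06)
})

test_that("equal-structure visits give non-significant paired h2 shifts", {
  # per-visit h2 for 15 proteins per replicate; the paired Wilcoxon between
  # visits should rarely reject when the two visits share the structure
  n_sig <- 0L
  reps <- 15
  for (r in seq_len(reps)) {
    coh <- simulate_cohort(cohort_design(36, 22, seed = 9000 + r))
    genes <- sprintf("P%02d", 1:15)
    Y <- simulate_protein_levels(coh, flat_profiles(genes), seed = 9100 + r)
    h2 <- vapply(1:2, function(v) {
      cv <- cohort_visit(coh, v)
      vapply(genes, function(gn)
        per_visit_fit(rank_normal(Y[gn, cv$sample_id]), cv)$proportions["g"],
        numeric(1))
    }, numeric(length(genes)))
    p <- wilcox.test(h2[, 1], h2[, 2], paired = TRUE, exact = FALSE)$p.value
    if (p < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig / reps, 0.15)
})

test_that("family component is the g + c share and is the stabler summary", {
  coh <- small_cohort(seed = 131)
  y <- rank_normal(simulate_protein_levels(
    coh, variance_profile("P", .4, .2, .1, .1, .2), seed = 132)[1, ])
  fit <- fit_twin_model(y, coh)
  fc <- family_component(fit)
  expect_equal(fc$of_total,
               unname(fit$proportions["g"] + fit$proportions["c"]))
  # swapping g and c leaves the family sum unchanged by construction
  expect_equal(sum(fit$proportions[c("g", "c")]),
               sum(fit$proportions[c("c", "g")]))
  # on a DZ-poor design, replicate scatter of family < scatter of h2
  est <- t(vapply(1:40, function(i) {
    coh <- simulate_cohort(cohort_design(30, 5, seed = 10000 + i))
    y <- rank_normal(simulate_protein_levels(
      coh, variance_profile("P", g = .3, c_ = .3, id = .1, w = .1, e = .2),
      seed = 10100 + i)[1, ])
    fit <- fit_twin_model(y, coh, n_starts = 3)
    c(h2 = fit$h2, fam = family_component(fit)$of_total)
  }, numeric(2)))
  expect_lt(sd(est[, "fam"]), sd(est[, "h2"]))
})

test_that("heritability CI honours boundaries and sample-size scaling", {
  # estimate at the zero boundary: lower limit is exactly 0
  coh <- simulate_cohort(cohort_design(60, 40, seed = 141))
  y0 <- rank_normal(simulate_protein_levels(
    coh, variance_profile("P", c_ = .4, e = .6), seed = 142)[1, ])
  fit0 <- fit_twin_model(y0, coh, n_starts = 3)
  if (fit0$h2 < 1e-6) {
    ci0 <- heritability_ci(fit0)
    expect_equal(ci0$lo, 0)
  }
  # interval widens as the cohort shrinks
  width <- vapply(c(360, 36), function(nmz) {
    coh <- simulate_cohort(cohort_design(nmz, round(nmz * 22 / 36),
                                         seed = 143))
    y <- rank_normal(simulate_protein_levels(
      coh, variance_profile("P", g = .5, c_ = .1, id = .1, w = .1, e = .2),
      seed = 144)[1, ])
    fit <- fit_twin_model(y, coh, n_starts = 3)
    ci <- heritability_ci(fit)
    ci$hi - ci$lo
  }, numeric(1))
  expect_lt(width[1], width[2])
})
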