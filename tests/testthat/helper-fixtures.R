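# Shared fixtures: small cohorts and profile shortcuts built in code.

small_cohort <- function(n_mz = 10, n_dz = 6, seed = 1L, ...) {
  simulate_cohort(cohort_design(n_mz, n_dz, seed = seed, ...))
}

flat_profiles <- function(genes, g = 0.3, c_ = 0.15, id = 0.15, w = 0.1,
                          e = 0.3) {
  do.call(variance_profiles, lapply(genes, function(gn)
    variance_profile(gn, g = g, c_ = c_, id = id, w = w, e = e)))
}

# Dense multivariate-normal log-likelihood with GLS-profiled fixed effects:
# the independent oracle for the family-block computation.
dense_mvn_loglik <- function(components, y, cohort) {
  X <- twinprot:::build_design(cohort)
  ok <- is.finite(y)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  cohort <- cohort[ok, , drop = FALSE]
  n <- length(y)
  S <- matrix(0, n, n)
  for (idx in split(seq_len(n), cohort$pair_id)) {
    M <- twinprot:::family_structure(
      cohort$zygosity[idx[1]],
      data.frame(twin = cohort$twin[idx], visit = cohort$visit[idx]))
    S[idx, idx] <- Reduce(`+`, Map(`*`, components[names(M)], M))
  }
  Si <- solve(S)
  beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       t(r) %*% Si %*% r))
}
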