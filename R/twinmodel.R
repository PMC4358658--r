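#' Rank-based inverse normal transformation
#'
#' Maps values through the Blom offset `(r - 3/8) / (n + 1/4)` of their
#' average-tie ranks into standard normal quantiles.  This is the standard
#' guard against non-normal trait distributions before variance-component
#' or association modelling; it is invariant under any strictly monotone
#' transformation of the input.
#'
#' @param x Numeric vector (NA allowed; returned as NA).
#' @return Numeric vector of the same length.
#' @examples
#' rank_normal(c(3, 1, 7))
#' @export
rank_normal <- function(x) {
  ok <- is.finite(x)
  v <- x[ok]
  if (length(v) < 2) stop("need at least 2 finite values")
  if (diff(range(v)) == 0) stop("all values identical: no ordering information")
  r <- rank(v, ties.method = "average")
  out <- x
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out
}

# ---- family covariance structure ------------------------------------------

# Structure matrices over the observed samples of one family.
# slots: data.frame with columns `twin` (1/2) and `visit`.
family_structure <- function(zygosity, slots) {
  same_ind <- outer(slots$twin, slots$twin, "==")
  same_vis <- outer(slots$visit, slots$visit, "==")
  kin <- ifelse(same_ind, 1, if (zygosity == "MZ") 1 else 0.5)
  d <- nrow(slots)
  list(
    g  = kin,
    c  = matrix(1, d, d),
    id = same_ind * 1,
    w  = same_vis * 1,
    e  = diag(d)
  )
}

#' Build the analytic covariance block of one twin family
#'
#' Returns \eqn{\Sigma = \sigma^2_g 2\Phi + \sigma^2_c C + \sigma^2_{id} ID
#' + \sigma^2_w W + \sigma^2_e I} over the family's samples, ordered as
#' (twin 1 visit 1, ..., twin 1 visit V, twin 2 visit 1, ...).  The kinship
#' entry \eqn{2\Phi} is 1 within an individual and within MZ pairs, and 1/2
#' between DZ co-twins; `C` is shared by the pair, `ID` by an individual
#' across visits, `W` by the pair within a visit.
#'
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param components Named numeric with non-negative entries `g`, `c`,
#'   `id`, `w`, `e`.
#' @param n_visits Visits per individual (default 2).
#' @return A symmetric positive semi-definite matrix of size
#'   `2 * n_visits`.
#' @examples
#' build_family_covariance("MZ", c(g = .4, c = .2, id = .2, w = .1, e = .1))
#' @export
build_family_covariance <- function(zygosity, components, n_visits = 2) {
  zygosity <- match.arg(zygosity, c("MZ", "DZ"))
  components <- components[c("g", "c", "id", "w", "e")]
  if (any(is.na(components))) stop("components must name g, c, id, w, e")
  if (any(components < 0)) stop("variance components must be non-negative")
  slots <- expand.grid(visit = seq_len(n_visits), twin = 1:2)[, 2:1]
  M <- family_structure(zygosity, slots)
  S <- Reduce(`+`, Map(`*`, components, M))
  rownames(S) <- colnames(S) <- sprintf("twin%d.v%d", slots$twin, slots$visit)
  S
}

# ---- sufficient statistics for the block likelihood -----------------------

# Groups families by (zygosity, observed-slot pattern) and precomputes, per
# pattern, the moment statistics that make one likelihood evaluation O(1)
# in the number of families:
#   Syy = sum_f y_f y_f'                       (d x d)
#   A2  = sum_f y_f (x) X_f  (Kronecker)       (d^2 x p)
#   T2  = sum_f X_f (x) X_f                    (d^2 x p^2)
# so that  y'S^-1y = <vec(S^-1), vec(Syy)>,  X'S^-1y = vec(S^-1)' A2,
# X'S^-1X = matrix(vec(S^-1)' T2, p, p).
make_prep <- function(y, X, cohort, comp_names = c("g", "c", "id", "w", "e")) {
  keep <- is.finite(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  cohort <- cohort[keep, , drop = FALSE]
  p <- ncol(X)
  fam <- split(seq_along(y), cohort$pair_id)
  pats <- new.env(parent = emptyenv())
  for (idx in fam) {
    zyg <- cohort$zygosity[idx[1]]
    slots <- data.frame(twin = cohort$twin[idx], visit = cohort$visit[idx])
    key <- paste(zyg, paste(slots$twin, slots$visit, sep = "v",
                            collapse = "_"))
    d <- length(idx)
    yf <- y[idx]; Xf <- X[idx, , drop = FALSE]
    if (!exists(key, pats)) {
      M <- family_structure(zyg, slots)[comp_names]
      assign(key, list(
        M = M,
        Mflat = vapply(M, as.vector, numeric(d * d)),  # d^2 x k
        d = d, n_fam = 0L,
        Syy = matrix(0, d, d), A2 = matrix(0, d * d, p),
        T2 = matrix(0, d * d, p * p),
        idx = list(), Y = NULL, Xs = list()
      ), pats)
    }
    pt <- get(key, pats)
    pt$n_fam <- pt$n_fam + 1L
    pt$Syy <- pt$Syy + tcrossprod(yf)
    pt$A2 <- pt$A2 + kronecker(matrix(yf, ncol = 1), Xf)
    pt$T2 <- pt$T2 + kronecker(Xf, Xf)
    pt$idx[[pt$n_fam]] <- idx
    pt$Xs[[pt$n_fam]] <- Xf
    pt$Y <- cbind(pt$Y, yf)
    assign(key, pt, pats)
  }
  list(patterns = as.list(pats), N = length(y), p = p,
       comp_names = comp_names, y = y, X = X, keep = keep,
       var_y = stats::var(y))
}

# Profiled negative log-likelihood (ML or REML) at variance components sig2.
# Returns attr "beta" with the GLS fixed effects.
prep_negll <- function(sig2, prep, reml = FALSE) {
  p <- prep$p
  ld_sum <- 0; ytSiy <- 0
  XtX <- matrix(0, p, p); Xty <- numeric(p)
  for (pt in prep$patterns) {
    Sigma <- matrix(pt$Mflat %*% sig2, pt$d, pt$d)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(structure(1e10, beta = rep(NA_real_, p)))
    Sinv <- chol2inv(ch)
    ld_sum <- ld_sum + pt$n_fam * 2 * sum(log(diag(ch)))
    ytSiy <- ytSiy + sum(Sinv * pt$Syy)
    v <- as.vector(Sinv)
    XtX <- XtX + matrix(crossprod(v, pt$T2), p, p)
    Xty <- Xty + drop(crossprod(v, pt$A2))
  }
  beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(beta)) return(structure(1e10, beta = rep(NA_real_, p)))
  quad <- ytSiy - sum(beta * Xty)          # GLS-profiled quadratic form
  if (quad < 0) quad <- 0
  val <- if (reml) {
    ldx <- determinant(XtX, logarithm = TRUE)$modulus
    0.5 * ((prep$N - p) * log(2 * pi) + ld_sum + ldx + quad)
  } else {
    0.5 * (prep$N * log(2 * pi) + ld_sum + quad)
  }
  structure(val, beta = beta)
}

# Maximise the likelihood over a constrained component vector.
#  fix_zero: components pinned at exactly 0.
#  h2: if non-NULL, the g share of the total is pinned at this value and g
#      is derived from the free components.
fit_core <- function(prep, reml = FALSE, fix_zero = character(),
                     h2 = NULL, n_starts = 5, seed = NULL,
                     start = NULL) {
  comp <- prep$comp_names
  free <- setdiff(comp, fix_zero)
  if (!is.null(h2)) free <- setdiff(free, "g")
  k <- length(free)
  expand <- function(u) {
    sig <- numeric(length(comp)); names(sig) <- comp
    sig[free] <- u
    if (!is.null(h2)) {
      s <- sum(sig[setdiff(comp, "g")])
      sig["g"] <- if (h2 >= 1) Inf else h2 / (1 - h2) * s
    }
    sig
  }
  obj <- function(u) as.numeric(prep_negll(expand(u), prep, reml))
  vt <- prep$var_y
  starts <- list()
  if (!is.null(start)) starts[[length(starts) + 1]] <- pmax(start[free], 1e-8)
  starts[[length(starts) + 1]] <- rep(vt / length(comp), k)
  if (n_starts > length(starts)) {
    rng <- if (!is.null(seed)) local_rng(seed) else NULL
    for (i in seq_len(n_starts - length(starts))) {
      w <- stats::rexp(k)
      starts[[length(starts) + 1]] <- vt * w / sum(w)
    }
    if (!is.null(rng)) rng$restore()
  }
  # two-stage search: coarse passes from every start, one refined pass
  # from the best coarse solution
  best <- NULL
  for (s0 in starts) {
    op <- tryCatch(
      stats::nlminb(s0, obj, lower = rep(0, k), upper = rep(50 * vt, k),
                    control = list(iter.max = 60, eval.max = 150,
                                   rel.tol = 1e-6)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  if (is.null(best)) stop("variance-component optimisation failed to start")
  op <- tryCatch(
    stats::nlminb(pmax(best$par, 0), obj, lower = rep(0, k),
                  upper = rep(50 * vt, k),
                  control = list(iter.max = 300, eval.max = 600)),
    error = function(e) NULL)
  if (!is.null(op) && op$objective <= best$objective) best <- op
  # boundary polish: freeze near-zero components at exactly zero and refit
  u <- pmax(best$par, 0)
  tot <- sum(expand(u))
  tiny <- free[u < 1e-6 * max(tot, 1e-12)]
  if (length(tiny) > 0 && length(tiny) < k) {
    sub <- setdiff(free, tiny)
    obj2 <- function(v) {
      u2 <- numeric(k); names(u2) <- free
      u2[sub] <- v
      obj(u2)
    }
    op2 <- tryCatch(
      stats::nlminb(u[match(sub, free)], obj2, lower = rep(0, length(sub)),
                    upper = rep(50 * vt, length(sub)),
                    control = list(iter.max = 300)),
      error = function(e) NULL)
    if (!is.null(op2) && op2$objective <= best$objective + 1e-6) {
      u[] <- 0
      u[match(sub, free)] <- pmax(op2$par, 0)
      best$objective <- min(best$objective, op2$objective)
      best$convergence <- op2$convergence
    }
  } else {
    u[u < 1e-10] <- 0
  }
  sig <- expand(u)
  nll <- prep_negll(sig, prep, reml)
  list(components = sig, loglik = -as.numeric(nll),
       beta = attr(nll, "beta"), convergence = best$convergence,
       n_starts = length(starts))
}

# Fixed-effect design matrix: intercept, plate dummies, time covariate and
# optional extra columns; rank-deficient columns are dropped.
build_design <- function(cohort, covariates = NULL) {
  X <- matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)"))
  pl <- droplevels(factor(cohort$plate))
  if (nlevels(pl) > 1) {
    D <- stats::model.matrix(~pl)[, -1, drop = FALSE]
    colnames(D) <- paste0("plate_", levels(pl)[-1])
    X <- cbind(X, D)
  }
  if (length(unique(cohort$time)) > 1)
    X <- cbind(X, time = cohort$time)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

# ---- user-facing fitting ---------------------------------------------------

#' Fit the longitudinal twin variance-components model to one trait
#'
#' Maximum-likelihood decomposition of a trait measured on twin pairs at
#' repeated visits into five variance components -- additive genetic (`g`),
#' common environment (`c`), individual environment (`id`),
#' longitudinal/visit (`w`) and residual (`e`) -- under the multivariate
#' normal model whose per-family covariance is built by
#' [build_family_covariance()].  Plate and the time-since-first-visit
#' covariate enter as fixed effects, profiled out by generalised least
#' squares inside every likelihood evaluation.  The likelihood is computed
#' family block by family block (families with missing samples contribute
#' their observed sub-block), and the optimiser runs from several starting
#' points with an exact-zero boundary polish, since components frequently
#' lie on the zero boundary.
#'
#' @param y Trait values, one per cohort row.  Rank-normalise first (see
#'   [rank_normal()]); a warning is emitted when the input does not look
#'   standardised.
#' @param cohort A `twin_cohort`.
#' @param covariates Optional extra fixed-effect columns (e.g. age).
#' @param reml Use REML instead of ML (default `FALSE`, plain ML).
#' @param n_starts Number of optimisation starts (1 moment-based + random
#'   restarts; default 5).
#' @param seed Seed for the random restarts.
#' @return An object of class `twin_fit`: variance components, fixed
#'   effects, log-likelihood, proportions of total and of biologically
#'   stable (`g+c+id+w`) variance, and convergence diagnostics.
#' @examples
#' coh <- simulate_cohort(cohort_design(20, 12, seed = 3))
#' y <- simulate_protein_levels(coh, variance_profile("P", g = .5, e = .5),
#'                              seed = 3)[1, ]
#' fit <- fit_twin_model(rank_normal(y), coh)
#' fit$proportions
#' @export
fit_twin_model <- function(y, cohort, covariates = NULL, reml = FALSE,
                           n_starts = 5, seed = 171L) {
  stopifnot(inherits(cohort, "twin_cohort"), length(y) == nrow(cohort))
  ok <- is.finite(y)
  if (sum(ok) < 8) stop("too few observed samples to fit the twin model")
  if (abs(mean(y[ok])) > 0.5 || abs(stats::sd(y[ok]) - 1) > 0.5)
    warning("trait does not look rank-normalised; consider rank_normal()")
  X <- build_design(cohort, covariates)
  prep <- make_prep(y, X, cohort)
  res <- fit_core(prep, reml = reml, n_starts = n_starts, seed = seed)
  finish_fit(res, prep, model = "longitudinal", reml = reml)
}

finish_fit <- function(res, prep, model, reml) {
  sig <- res$components
  tot <- sum(sig)
  prop <- if (tot > 0) sig / tot else sig * NA
  stable_names <- setdiff(names(sig), "e")
  stot <- sum(sig[stable_names])
  stable <- if (stot > 0) sig[stable_names] / stot else sig[stable_names] * NA
  beta <- res$beta
  names(beta) <- colnames(prep$X)
  structure(list(
    components = sig, beta = beta, loglik = res$loglik,
    total = tot, proportions = prop, stable_proportions = stable,
    h2 = unname(prop["g"]),
    model = model, reml = reml,
    convergence = list(code = res$convergence, n_starts = res$n_starts),
    prep = prep
  ), class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, digits = 4, ...) {
  cat(sprintf("twin model fit (%s, %s), logLik = %.3f\n", x$model,
              if (x$reml) "REML" else "ML", x$loglik))
  m <- rbind(`sigma^2` = x$components, proportion = x$proportions)
  print(round(m, digits))
  invisible(x)
}

#' Evaluate the profiled block log-likelihood at given components
#'
#' Computes the Gaussian log-likelihood of a trait under the twin
#' covariance structure at fixed variance components, with the fixed
#' effects profiled by generalised least squares, accumulated family block
#' by family block.  Exposed mainly so the block computation can be checked
#' against a dense multivariate-normal evaluation.
#'
#' @inheritParams fit_twin_model
#' @param components Named non-negative variances `g`, `c`, `id`, `w`, `e`.
#' @return The log-likelihood (numeric scalar) with the GLS fixed-effect
#'   estimates as attribute `"beta"`.
#' @export
twin_model_loglik <- function(components, y, cohort, covariates = NULL,
                              reml = FALSE) {
  X <- build_design(cohort, covariates)
  prep <- make_prep(y, X, cohort)
  nll <- prep_negll(components[prep$comp_names], prep, reml)
  structure(-as.numeric(nll), beta = attr(nll, "beta"))
}

#' Profile-likelihood confidence interval for heritability
#'
#' Profiles the log-likelihood over the heritability share
#' \eqn{h^2 = \sigma^2_g / \sigma^2_{tot}} (all other components
#' re-maximised at each candidate value) and returns the interval where the
#' profile stays within \eqn{\chi^2_1(level)/2} of the maximum, clipped to
#' \eqn{[0, 1]}.  When the profile fails to bracket, a delta-method
#' interval is returned and flagged in the `method` field.
#'
#' @param fit A converged `twin_fit`.
#' @param level Confidence level (default 0.95).
#' @return List with `lo`, `hi`, `level`, `method`
#'   (`"profile"` or `"delta"`).
#' @export
heritability_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "twin_fit"))
  prep <- fit$prep
  cut <- fit$loglik - stats::qchisq(level, 1) / 2
  h2 <- fit$h2
  warm <- fit$components
  prof <- function(p) {
    r <- fit_core(prep, reml = fit$reml, h2 = p, n_starts = 1,
                  start = warm, seed = 7L)
    warm <<- r$components
    r$loglik
  }
  f <- function(p) prof(p) - cut
  out <- tryCatch({
    lo <- if (h2 <= 1e-8 || f(1e-8) >= 0) 0 else
      stats::uniroot(f, c(1e-8, h2), tol = 5e-3)$root
    warm <- fit$components
    hi <- if (h2 >= 0.999 || f(0.999) >= 0) 1 else
      stats::uniroot(f, c(h2, 0.999), tol = 5e-3)$root
    list(lo = max(0, lo), hi = min(1, hi), level = level,
         method = "profile")
  }, error = function(e) NULL)
  if (!is.null(out)) return(out)
  # delta-method fallback on the h2 ratio
  sig <- pmax(fit$components, 1e-8)
  H <- tryCatch(stats::optimHess(sig, function(s)
    as.numeric(prep_negll(s, prep, fit$reml))), error = function(e) NULL)
  se <- NA_real_
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      tot <- sum(sig)
      # d(h2)/d(sigma_k) = (1{k=g} * tot - sigma_g) / tot^2
      grad <- (as.numeric(names(sig) == "g") * tot - sig["g"]) / tot^2
      se <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
    }
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lo = max(0, fit$h2 - z * se), hi = min(1, fit$h2 + z * se),
       level = level, method = "delta")
}

#' Boundary likelihood-ratio test for one variance component
#'
#' Tests whether a single variance component is zero by refitting the model
#' with that component pinned at the boundary and comparing
#' \eqn{\Lambda = 2(\ell_{full} - \ell_{reduced})} against the 50:50
#' mixture of \eqn{\chi^2_0} and \eqn{\chi^2_1} appropriate for a variance
#' bounded below at zero: p = 1 when \eqn{\Lambda = 0}, otherwise
#' \eqn{p = \tfrac12 P(\chi^2_1 \ge \Lambda)}.
#'
#' @param fit A `twin_fit`.
#' @param component One of the fit's component names (e.g. `"g"`).
#' @return List with `lambda`, `p`, `loglik_reduced`.
#' @export
lrt_component <- function(fit, component) {
  stopifnot(inherits(fit, "twin_fit"))
  component <- match.arg(component, names(fit$components))
  red <- fit_core(fit$prep, reml = fit$reml, fix_zero = component,
                  n_starts = 5, start = fit$components, seed = 11L)
  lam <- 2 * (fit$loglik - red$loglik)
  if (lam < -1e-6) {
    red2 <- fit_core(fit$prep, reml = fit$reml, fix_zero = component,
                     n_starts = 10, seed = 13L)
    if (red2$loglik > red$loglik) red <- red2
    lam <- 2 * (fit$loglik - red$loglik)
  }
  lam <- max(lam, 0)
  p <- if (lam <= 1e-10) 1 else 0.5 * stats::pchisq(lam, 1, lower.tail = FALSE)
  list(lambda = lam, p = p, loglik_reduced = red$loglik)
}

#' Flag proteins significantly affected by each variance component
#'
#' A component is called significant for a protein when its proportion of
#' total variance exceeds 0.25 or its boundary LRT p-value is below 0.01.
#'
#' @param fits A data.frame as returned by [decompose_proteins()] with
#'   proportion columns `prop_<comp>` and p-value columns `p_<comp>`.
#' @param components Components to classify (default the four biological
#'   ones).
#' @param prop_threshold,p_threshold The two rule thresholds.
#' @return Named list per component with the significant protein ids and a
#'   `counts` vector.
#' @export
classify_significant <- function(fits, components = c("g", "c", "id", "w"),
                                 prop_threshold = 0.25, p_threshold = 0.01) {
  out <- lapply(components, function(k) {
    prop <- fits[[paste0("prop_", k)]]
    pv <- fits[[paste0("p_", k)]]
    if (is.null(pv)) pv <- rep(1, nrow(fits))
    fits$protein[which(prop > prop_threshold | pv < p_threshold)]
  })
  names(out) <- components
  out$counts <- vapply(out[components], length, integer(1))
  out
}

#' Fit the single-visit twin model
#'
#' With one sample per individual the individual-environment and visit
#' components are structurally confounded with the residual and the
#' common-environment components, so the model reduces to three components:
#' additive genetic (`g`), pair-shared (`fam`, absorbing common environment
#' and the visit effect) and residual (`e`).
#'
#' @param y Trait values, one per row of the restricted cohort.
#' @param cohort A `twin_cohort` restricted to a single visit (see
#'   [cohort_visit()]).
#' @param ... Passed to the optimiser (`n_starts`, `seed`, `reml`).
#' @return A `twin_fit` with components `g`, `fam`, `e`.
#' @export
per_visit_fit <- function(y, cohort, reml = FALSE, n_starts = 3,
                          seed = 19L) {
  stopifnot(inherits(cohort, "twin_cohort"), length(y) == nrow(cohort))
  if (length(unique(cohort$visit)) != 1)
    stop("cohort must be restricted to a single visit; see cohort_visit()")
  if (anyDuplicated(cohort$individual_id[is.finite(y)]))
    stop("one sample per individual expected")
  X <- build_design(cohort)
  # map the three-component model onto the structure builder: g -> kinship,
  # fam -> all-ones pair block, e -> identity
  prep <- make_prep(y, X, cohort, comp_names = c("g", "c", "e"))
  res <- fit_core(prep, reml = reml, n_starts = n_starts, seed = seed)
  names(res$components) <- c("g", "fam", "e")
  fit <- finish_fit(res, prep, model = "single_visit", reml = reml)
  names(fit$components) <- names(fit$proportions) <- c("g", "fam", "e")
  names(fit$stable_proportions) <- c("g", "fam")
  fit
}

#' Family component of a twin fit
#'
#' The family effect -- the sum of the additive genetic and
#' common-environment components -- is estimated more robustly than either
#' alone in small twin samples, where the two are hard to separate.
#'
#' @param fit A `twin_fit`.
#' @return List with `of_total` (share of total variance) and `of_stable`
#'   (share of the biologically stable variance).
#' @export
family_component <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"))
  fam_names <- intersect(c("g", "c", "fam"), names(fit$components))
  list(of_total = unname(sum(fit$proportions[fam_names])),
       of_stable = unname(sum(fit$stable_proportions[
         intersect(fam_names, names(fit$stable_proportions))])))
}

#' Decompose every row of a protein matrix
#'
#' Applies [rank_normal()] and [fit_twin_model()] to each protein and
#' returns a tidy per-protein table of components, proportions and,
#' optionally, confidence intervals and boundary LRT p-values.
#'
#' @param proteins Numeric matrix, proteins x samples (columns matching
#'   `cohort$sample_id`).
#' @param cohort A `twin_cohort`.
#' @param rank_normalise Apply the rank-normal transformation per protein
#'   (default `TRUE`).
#' @param ci Compute the 95% heritability profile interval per protein.
#' @param lrt Components for which to compute boundary LRT p-values
#'   (character vector, e.g. `c("g", "w")`; default none).
#' @param ... Passed to [fit_twin_model()].
#' @return A data.frame, one row per protein, with columns `protein`,
#'   `sigma2_*`, `prop_*`, `stable_*`, `loglik`, `h2`, and optionally
#'   `h2_lo`/`h2_hi` and `p_*`.
#' @export
decompose_proteins <- function(proteins, cohort, rank_normalise = TRUE,
                               ci = FALSE, lrt = character(), ...) {
  stopifnot(is.matrix(proteins), ncol(proteins) == nrow(cohort))
  rows <- lapply(rownames(proteins), function(pr) {
    y <- proteins[pr, ]
    if (rank_normalise) y <- rank_normal(y)
    fit <- fit_twin_model(y, cohort, ...)
    row <- data.frame(protein = pr, t(fit$components), loglik = fit$loglik,
                      h2 = fit$h2, stringsAsFactors = FALSE)
    names(row)[2:6] <- paste0("sigma2_", names(fit$components))
    pr_prop <- as.list(fit$proportions)
    names(pr_prop) <- paste0("prop_", names(fit$proportions))
    st <- as.list(fit$stable_proportions)
    names(st) <- paste0("stable_", names(fit$stable_proportions))
    row <- cbind(row, pr_prop, st)
    if (ci) {
      iv <- heritability_ci(fit)
      row$h2_lo <- iv$lo; row$h2_hi <- iv$hi; row$ci_method <- iv$method
    }
    for (k in lrt) row[[paste0("p_", k)]] <- lrt_component(fit, k)$p
    row
  })
  do.call(rbind, rows)
}
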