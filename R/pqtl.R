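#' Remove the leading principal components of a protein matrix
#'
#' Removes unknown batch structure before association mapping: the top `k`
#' sample-space principal components of the protein-centred matrix are
#' regressed out of every protein, leaving residuals orthogonal to those
#' components.
#'
#' @param proteins Numeric matrix, proteins x samples (complete).
#' @param k Number of components to remove (default 10); must be smaller
#'   than both matrix dimensions.
#' @return Matrix of the same shape; each row is centred and orthogonal to
#'   the removed components.
#' @export
regress_out_pcs <- function(proteins, k = 10) {
  stopifnot(is.matrix(proteins), !anyNA(proteins))
  M <- t(proteins)                       # samples x proteins
  M <- sweep(M, 2, colMeans(M))          # centre each protein
  if (k == 0) return(t(M))
  if (k >= min(dim(M)))
    stop("k must be smaller than both dimensions (rank at most ",
         min(dim(M)), ")")
  sv <- svd(M, nu = k, nv = 0)
  U <- sv$u[, seq_len(k), drop = FALSE]
  R <- M - U %*% crossprod(U, M)
  t(R)
}

#' Family-structure-adjusted residuals of a single-visit trait
#'
#' Fits the single-visit twin model ([per_visit_fit()]) and removes the
#' family structure by whitening each family's fixed-effect residuals with
#' the Cholesky factor of its fitted covariance block,
#' \eqn{L^{-1}(y - X\hat\beta)} with \eqn{LL' = \hat\Sigma}, so the
#' returned residuals carry no within-family correlation; they are then
#' rank-normalised.  When the family variance is estimated at zero this
#' reduces to ordinary centred residuals.  If the model fit fails,
#' pair-mean-centred residuals are used instead and flagged.
#'
#' @param y Trait values, one per row of the single-visit cohort.
#' @param cohort A `twin_cohort` restricted to one visit.
#' @param rank_normalise Rank-normalise the residuals (default `TRUE`).
#' @return Named numeric vector (names = individual ids) with attribute
#'   `"method"` (`"whitened"` or `"pair_centered"`).
#' @export
polygenic_residuals <- function(y, cohort, rank_normalise = TRUE) {
  stopifnot(length(y) == nrow(cohort))
  fit <- tryCatch(suppressWarnings(per_visit_fit(y, cohort)),
                  error = function(e) NULL)
  res <- rep(NA_real_, length(y))
  method <- "whitened"
  if (!is.null(fit)) {
    prep <- fit$prep
    sig <- unname(fit$components)        # order matches prep$comp_names
    beta <- fit$beta
    orig <- which(prep$keep)   # kept-subset index -> original row
    for (pt in prep$patterns) {
      Sigma <- Reduce(`+`, Map(`*`, sig, pt$M))
      L <- t(chol(Sigma))
      for (f in seq_len(pt$n_fam)) {
        idx <- pt$idx[[f]]
        r <- prep$y[idx] - drop(pt$Xs[[f]] %*% beta)
        res[orig[idx]] <- forwardsolve(L, r)
      }
    }
  } else {
    method <- "pair_centered"
    pm <- stats::ave(y, cohort$pair_id)
    res <- y - pm
  }
  if (rank_normalise) res <- rank_normal(res)
  names(res) <- cohort$individual_id
  attr(res, "method") <- method
  res
}

# Per-SNP simple linear regression of trait on additive genotype.
# Returns slope, p and |r| per SNP (columns of G); monomorphic SNPs get NA.
snp_regression <- function(y, G) {
  n <- length(y)
  gs <- apply(G, 2, stats::sd)
  ys <- stats::sd(y)
  r <- suppressWarnings(stats::cor(y, G))[1, ]
  r[gs == 0] <- NA
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  slope <- r * ys / ifelse(gs == 0, NA, gs)
  data.frame(snp_id = colnames(G), slope = slope, p = p, abs_r = abs(r),
             stringsAsFactors = FALSE)
}

#' Best cis association per gene
#'
#' Runs a simple linear regression of a family-adjusted trait on every SNP
#' inside the window around the gene's transcription start site (inclusive
#' at both edges, 1-based coordinates) and keeps the best association:
#' smallest nominal p, ties broken by larger `|slope|` then by SNP id.
#'
#' @param trait Named numeric vector (names = individual ids).
#' @param genotypes Genotype matrix, individuals x SNPs (0/1/2).
#' @param snp_ann Data.frame with columns `snp_id`, `chrom`, `pos`.
#' @param tss Data.frame with columns `gene`, `chrom`, `tss`.
#' @param window Half-width of the cis window in base pairs (default
#'   1000).
#' @return Data.frame, one row per gene with at least one polymorphic SNP
#'   in the window: `gene`, `snp_id`, `slope`, `p`, `n_snps`.  Genes with
#'   no usable SNP are omitted.
#' @export
cis_scan <- function(trait, genotypes, snp_ann, tss, window = 1000) {
  stopifnot(all(names(trait) %in% rownames(genotypes)))
  G_all <- genotypes[names(trait), , drop = FALSE]
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    sel <- snp_ann$chrom == tss$chrom[i] &
      abs(snp_ann$pos - tss$tss[i]) <= window
    ids <- snp_ann$snp_id[sel]
    if (length(ids) == 0) return(NULL)
    fit <- snp_regression(trait, G_all[, ids, drop = FALSE])
    fit <- fit[!is.na(fit$p), , drop = FALSE]
    if (nrow(fit) == 0) return(NULL)
    fit <- fit[order(fit$p, -abs(fit$slope), fit$snp_id), , drop = FALSE]
    data.frame(gene = tss$gene[i], snp_id = fit$snp_id[1],
               slope = fit$slope[1], p = fit$p[1], n_snps = nrow(fit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Permutation-based empirical p-value for one gene's best cis SNP
#'
#' Shuffles the trait over individuals `B` times, repeats the
#' best-SNP-per-gene scan for each shuffle and reports
#' `(1 + #[perm best >= observed best]) / (B + 1)`, where the comparison is
#' on the absolute best correlation (equivalent to comparing the smallest
#' nominal p, and invariant to any monotone transform of the per-SNP
#' statistic).  The permutation stream is reproducible from
#' `(seed, gene)`.
#'
#' @param trait Named numeric vector (names = individual ids).
#' @param genotypes Genotype matrix restricted or not; only the columns
#'   in `snp_ids` are used.
#' @param snp_ids SNPs of the gene's cis window.
#' @param gene Gene id (keys the per-gene permutation stream).
#' @param B Number of permutations (>= 100).
#' @param seed Base seed.
#' @return List with `empirical_p`, `observed_abs_r`, `B`.
#' @export
permutation_pvalue <- function(trait, genotypes, snp_ids, gene,
                               B = 20000, seed = 1L) {
  stopifnot(B >= 100)
  G <- genotypes[names(trait), snp_ids, drop = FALSE]
  gs <- apply(G, 2, stats::sd)
  G <- G[, gs > 0, drop = FALSE]
  if (ncol(G) == 0) stop("no polymorphic SNP for gene ", gene)
  Gs <- scale(G)
  ys <- as.vector(scale(trait))
  n <- length(ys)
  obs <- max(abs(crossprod(Gs, ys) / (n - 1)))
  rng <- local_rng(derive_seed(seed, gene))
  on.exit(rng$restore())
  P <- matrix(0, n, B)
  for (b in seq_len(B)) P[, b] <- ys[sample.int(n)]
  best <- apply(abs(crossprod(Gs, P) / (n - 1)), 2, max)
  list(empirical_p = (1 + sum(best >= obs)) / (B + 1),
       observed_abs_r = obs, B = B)
}

#' Fisher combination of two per-visit p-values
#'
#' Combines the empirical p-values from the two visits with Fisher's
#' method, \eqn{X = -2(\ln p_1 + \ln p_2)}, \eqn{p = P(\chi^2_4 \ge X)},
#' only when the SNP influences the protein in the same direction at both
#' visits; discordant associations are not combined and receive p = 1.
#'
#' @param p1,p2 Per-visit p-values in (0, 1].
#' @param sign1,sign2 Signs of the per-visit slopes.
#' @param p_floor Values of 0 are clamped here with a warning (use
#'   `1/(B+1)` of the permutation scheme).
#' @return The combined p-value.
#' @export
fisher_combine <- function(p1, p2, sign1, sign2, p_floor = 1 / 20001) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) stop("p-values outside [0, 1]")
  if (p1 == 0 || p2 == 0) {
    warning("p-value of 0 clamped to ", format(p_floor))
    p1 <- max(p1, p_floor); p2 <- max(p2, p_floor)
  }
  if (sign1 * sign2 <= 0) return(1)
  X <- -2 * (log(p1) + log(p2))
  stats::pchisq(X, df = 4, lower.tail = FALSE)
}

#' Storey q-values
#'
#' Implements the Storey false-discovery-rate procedure: the null
#' proportion \eqn{\hat\pi_0} is estimated by a cubic smoothing spline of
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))} over the
#' grid \eqn{\lambda = 0.05, \dots, 0.95}, evaluated at the largest
#' \eqn{\lambda}; q-values are the step-down minima
#' \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j}.  With fewer
#' than 20 p-values \eqn{\hat\pi_0} is fixed at 1 (the
#' Benjamini-Hochberg special case) and flagged.
#'
#' @param p Vector of p-values in [0, 1].
#' @param fdr Significance threshold on q (default 0.10).
#' @param pi0 Optional fixed null proportion (overrides estimation).
#' @return List with `qvalues`, `pi0`, `pi0_method`, `significant`
#'   (logical at `q <= fdr`).
#' @export
qvalue_storey <- function(p, fdr = 0.10, pi0 = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  method <- "fixed"
  if (is.null(pi0)) {
    if (m < 20) {
      pi0 <- 1
      method <- "small_m_bh"
    } else {
      lam <- seq(0.05, 0.95, by = 0.05)
      pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
      pi0 <- min(max(pi0, 1e-8), 1)
      method <- "smoother"
    }
  }
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  list(qvalues = out, pi0 = pi0, pi0_method = method,
       significant = out <= fdr)
}

#' Variance explained by a pQTL and its family-component share
#'
#' @param y Protein values (any consistent sample set).
#' @param g Additive genotypes aligned to `y`.
#' @param fit Converged longitudinal `twin_fit` for the protein (for the
#'   family component \eqn{\hat h^2 + \hat c^2}).
#' @return List with `pve` (regression R^2 of protein on genotype),
#'   `family_fraction` (`pve / (h2 + c2)`, capped at 1 and flagged via
#'   `capped`; `NA` when the family component is zero).
#' @export
variance_explained <- function(y, g, fit) {
  ok <- is.finite(y) & is.finite(g)
  pve <- if (stats::sd(g[ok]) == 0) 0 else
    suppressWarnings(stats::cor(y[ok], g[ok])^2)
  fam <- sum(fit$proportions[intersect(c("g", "c", "fam"),
                                       names(fit$proportions))])
  if (fam <= 0) return(list(pve = pve, family_fraction = NA_real_,
                            capped = FALSE))
  fr <- pve / fam
  list(pve = pve, family_fraction = min(fr, 1), capped = fr > 1)
}

#' Mean-p enrichment test for a candidate SNP set
#'
#' Tests whether a set of candidate associations is enriched for small
#' p-values by comparing the observed mean p-value with the distribution
#' of means of the same number of iid Uniform(0,1) draws.
#'
#' @param p Candidate p-values (length k >= 1).
#' @param n_null Number of null mean draws (default 1e5).
#' @param seed Integer seed.
#' @return List with `observed_mean`, `enrichment_p` (plus-one corrected
#'   fraction of null means at or below the observed mean).
#' @export
mean_p_enrichment <- function(p, n_null = 1e5, seed = 41L) {
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1))
  k <- length(p)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  nulls <- colMeans(matrix(stats::runif(n_null * k), k, n_null))
  list(observed_mean = mean(p),
       enrichment_p = (1 + sum(nulls <= mean(p))) / (n_null + 1))
}

#' Full cis-pQTL scan over a protein panel
#'
#' Runs the complete mapping procedure: per visit, the leading principal
#' components are regressed out of the protein matrix, each protein is
#' reduced to family-structure-adjusted rank-normalised residuals, the cis
#' window around the gene's TSS is scanned for the best SNP, and an
#' empirical p-value is obtained by permutation.  The two visits are then
#' combined with Fisher's method for direction-concordant associations and
#' significance is called by Storey q-value at the requested FDR.
#'
#' @param proteins Numeric matrix, proteins x samples; row names must
#'   match `tss$gene`.
#' @param cohort The full two-visit `twin_cohort`.
#' @param genotypes Genotype matrix, individuals x SNPs.
#' @param snp_ann Data.frame `snp_id`, `chrom`, `pos`.
#' @param tss Data.frame `gene`, `chrom`, `tss`.
#' @param k_pcs Principal components removed per visit (default 10).
#' @param window Cis window half-width in bp (default 1000).
#' @param B Permutations per gene and visit (default 20000).
#' @param fdr q-value threshold (default 0.10).
#' @param seed Base seed for the permutation streams.
#' @param fits Optional [decompose_proteins()] table for the
#'   variance-explained accounting (adds `pve` and `family_fraction`).
#' @return Data.frame, one row per testable gene: per-visit best SNP,
#'   slope, nominal and empirical p, the combined p, q-value,
#'   `significant`, and optionally `pve` / `family_fraction`.
#' @export
map_pqtls <- function(proteins, cohort, genotypes, snp_ann, tss,
                      k_pcs = 10, window = 1000, B = 20000, fdr = 0.10,
                      seed = 1L, fits = NULL) {
  stopifnot(max(cohort$visit) >= 2)
  visits <- 1:2
  per_visit <- lapply(visits, function(v) {
    cv <- cohort_visit(cohort, v)
    mat <- proteins[, cv$sample_id, drop = FALSE]
    mat <- regress_out_pcs(mat, k = k_pcs)
    res <- lapply(rownames(mat), function(pr)
      polygenic_residuals(mat[pr, ], cv))
    names(res) <- rownames(mat)
    res
  })
  rows <- lapply(tss$gene, function(gn) {
    if (!gn %in% rownames(proteins)) return(NULL)
    ti <- tss[tss$gene == gn, , drop = FALSE]
    sel <- snp_ann$chrom == ti$chrom & abs(snp_ann$pos - ti$tss) <= window
    ids <- snp_ann$snp_id[sel]
    ids <- ids[apply(genotypes[, ids, drop = FALSE], 2, stats::sd) > 0]
    if (length(ids) == 0) {
      message("gene ", gn, ": no polymorphic SNP in the cis window, skipped")
      return(NULL)
    }
    vis <- lapply(visits, function(v) {
      tr <- per_visit[[v]][[gn]]
      sc <- cis_scan(tr, genotypes, snp_ann[sel, , drop = FALSE], ti,
                     window = window)
      pp <- permutation_pvalue(tr, genotypes, ids, paste(gn, v),
                               B = B, seed = seed)
      list(scan = sc, emp = pp$empirical_p, trait = tr)
    })
    # report SNP: the best nominal association over both visits, its slope
    # evaluated at both visits for the direction-concordance check
    best_v <- which.min(vapply(vis, function(z) z$scan$p, numeric(1)))
    snp <- vis[[best_v]]$scan$snp_id
    slopes <- vapply(visits, function(v) {
      tr <- vis[[v]]$trait
      g <- genotypes[names(tr), snp]
      if (stats::sd(g) == 0) return(0)
      stats::cov(tr, g) / stats::var(g)
    }, numeric(1))
    pc <- fisher_combine(vis[[1]]$emp, vis[[2]]$emp, slopes[1], slopes[2],
                         p_floor = 1 / (B + 1))
    data.frame(gene = gn, report_snp = snp,
               snp_v1 = vis[[1]]$scan$snp_id, snp_v2 = vis[[2]]$scan$snp_id,
               p_nom_v1 = vis[[1]]$scan$p, p_nom_v2 = vis[[2]]$scan$p,
               emp_p_v1 = vis[[1]]$emp, emp_p_v2 = vis[[2]]$emp,
               slope_v1 = slopes[1], slope_v2 = slopes[2],
               concordant = slopes[1] * slopes[2] > 0,
               p_combined = pc, n_snps = length(ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(out)
  qv <- qvalue_storey(out$p_combined, fdr = fdr)
  out$qvalue <- qv$qvalues
  out$significant <- qv$significant
  attr(out, "pi0") <- qv$pi0
  if (!is.null(fits)) {
    out$pve <- NA_real_; out$family_fraction <- NA_real_
    for (i in seq_len(nrow(out))) {
      gn <- out$gene[i]
      fr <- fits[fits$protein == gn, , drop = FALSE]
      if (nrow(fr) == 0) next
      y <- proteins[gn, ]
      g <- genotypes[cohort$individual_id, out$report_snp[i]]
      fam <- fr$prop_g + fr$prop_c
      pve <- suppressWarnings(stats::cor(y, g)^2)
      out$pve[i] <- pve
      out$family_fraction[i] <- if (fam > 0) min(pve / fam, 1) else NA_real_
    }
  }
  out
}
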