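#' Simulate protein log-intensities with a known twin variance structure
#'
#' For each protein, values are drawn through latent effects so that the
#' per-family covariance is exactly
#' \deqn{\Sigma = \sigma^2_g\,2\Phi + \sigma^2_c\,C + \sigma^2_{id}\,ID +
#'   \sigma^2_w\,W + \sigma^2_e\,I,}
#' where \eqn{2\Phi} is the expected kinship (1 within MZ pairs, 1/2 within
#' DZ pairs, 1 within an individual across visits), `C` is shared by the
#' whole pair, `ID` by the same individual across visits, `W` by the pair
#' within one visit and `I` is residual.  The DZ additive-genetic effect is
#' built as \eqn{\sqrt{1/2}\,g_{shared} + \sqrt{1/2}\,g_{unique}}, giving
#' correlation exactly 1/2.  Optional fixed plate offsets and a linear time
#' trend exercise the fixed-effect machinery of the fitter.
#'
#' @param cohort A `twin_cohort` from [simulate_cohort()].
#' @param profiles A `variance_profile` data.frame (one row per protein).
#' @param seed Integer seed.
#' @param plate_effects Optional numeric vector of per-plate fixed offsets
#'   (recycled over plate levels; default all zero).
#' @param beta_time Fixed-effect slope on the time covariate (default 0).
#' @return A numeric matrix, proteins x samples (log10-intensity scale,
#'   zero mean apart from fixed effects), with dimnames.
#' @examples
#' coh <- simulate_cohort(cohort_design(4, 3, seed = 7))
#' y <- simulate_protein_levels(coh, reference_variance_profiles(), seed = 7)
#' dim(y)
#' @export
simulate_protein_levels <- function(cohort, profiles, seed = 1L,
                                    plate_effects = NULL, beta_time = 0) {
  stopifnot(inherits(cohort, "twin_cohort"))
  pm <- as_profile_matrix(profiles)
  n <- nrow(cohort)
  pair <- factor(cohort$pair_id, levels = unique(cohort$pair_id))
  indiv <- factor(cohort$individual_id, levels = unique(cohort$individual_id))
  pvis <- factor(paste(cohort$pair_id, cohort$visit, sep = ":"))
  zyg_pair <- cohort$zygosity[!duplicated(cohort$pair_id)]
  is_dz <- zyg_pair[as.integer(pair)] == "DZ"   # per sample

  plate_off <- rep(0, nlevels(cohort$plate))
  if (!is.null(plate_effects))
    plate_off <- rep_len(plate_effects, nlevels(cohort$plate))
  fixed <- plate_off[as.integer(cohort$plate)] + beta_time * cohort$time

  rng <- local_rng(seed)
  on.exit(rng$restore())
  out <- matrix(NA_real_, nrow(pm), n,
                dimnames = list(rownames(pm), cohort$sample_id))
  for (p in seq_len(nrow(pm))) {
    s <- sqrt(pm[p, ])
    # additive genetic: shared draw per pair + unique draw per individual,
    # mixed with weight sqrt(1/2) for DZ twin-2 relative to twin-1 lineage
    g_shared <- stats::rnorm(nlevels(pair))[as.integer(pair)]
    g_unique <- stats::rnorm(nlevels(indiv))[as.integer(indiv)]
    g <- g_shared
    g[is_dz] <- sqrt(0.5) * g_shared[is_dz] + sqrt(0.5) * g_unique[is_dz]
    c_eff <- stats::rnorm(nlevels(pair))[as.integer(pair)]
    id_eff <- stats::rnorm(nlevels(indiv))[as.integer(indiv)]
    w_eff <- stats::rnorm(nlevels(pvis))[as.integer(pvis)]
    e_eff <- stats::rnorm(n)
    out[p, ] <- s["g"] * g + s["c"] * c_eff + s["id"] * id_eff +
      s["w"] * w_eff + s["e"] * e_eff + fixed
  }
  out
}

#' Describe a cis-SNP to simulate
#'
#' @param snp_id SNP identifier.
#' @param gene Gene (protein) the SNP sits near; used to place it relative
#'   to that gene's transcription start site.
#' @param offset Signed base-pair offset from the TSS.
#' @param maf Minor-allele frequency in (0.01, 0.5] (variants below 1%
#'   would fail the usual genotyping QC and are rejected).
#' @param pve Fraction of the target protein's variance explained by the
#'   additive SNP effect, in [0, 1).
#' @return A one-row `data.frame` of class `genotype_spec`.
#' @export
genotype_spec <- function(snp_id, gene, offset = 0L, maf = 0.3, pve = 0) {
  if (maf < 0.01 || maf > 0.5) stop("maf must lie in [0.01, 0.5]")
  if (pve < 0 || pve >= 1) stop("pve must lie in [0, 1)")
  out <- data.frame(snp_id = as.character(snp_id), gene = as.character(gene),
                    offset = as.integer(offset), maf = maf, pve = pve,
                    stringsAsFactors = FALSE)
  class(out) <- c("genotype_spec", "data.frame")
  out
}

#' Simulate biallelic genotypes for a twin cohort
#'
#' One genotype per individual (constant across visits), additive 0/1/2
#' coding.  MZ co-twins receive identical genotypes.  DZ co-twins are built
#' by simulating two parents in Hardy-Weinberg equilibrium at the given
#' allele frequency and transmitting one allele from each parent to each
#' twin independently, so the expected genotypic correlation between DZ
#' sisters is 1/2.
#'
#' @param cohort A `twin_cohort`.
#' @param specs A `genotype_spec` data.frame (one row per SNP), or anything
#'   accepted by `rbind` of such rows.
#' @param seed Integer seed.
#' @return Integer matrix, individuals x SNPs, with dimnames.
#' @export
simulate_genotypes <- function(cohort, specs, seed = 1L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  specs <- as.data.frame(specs)
  if (any(specs$maf < 0.01 | specs$maf > 0.5))
    stop("maf must lie in [0.01, 0.5]")
  ind <- cohort[!duplicated(cohort$individual_id),
                c("individual_id", "pair_id", "zygosity", "twin")]
  pairs <- ind[ind$twin == 1, c("pair_id", "zygosity")]
  n_pair <- nrow(pairs)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  G <- matrix(NA_integer_, nrow(ind), nrow(specs),
              dimnames = list(ind$individual_id, specs$snp_id))
  for (s in seq_len(nrow(specs))) {
    f <- specs$maf[s]
    # parental alleles per pair: mother (a1, a2), father (a3, a4)
    al <- matrix(stats::runif(4 * n_pair) < f, n_pair, 4)
    mz <- pairs$zygosity == "MZ"
    # each twin draws one maternal and one paternal allele
    pick_m1 <- stats::runif(n_pair) < 0.5
    pick_p1 <- stats::runif(n_pair) < 0.5
    pick_m2 <- stats::runif(n_pair) < 0.5
    pick_p2 <- stats::runif(n_pair) < 0.5
    gm1 <- ifelse(pick_m1, al[, 1], al[, 2]) + ifelse(pick_p1, al[, 3], al[, 4])
    gm2 <- ifelse(pick_m2, al[, 1], al[, 2]) + ifelse(pick_p2, al[, 3], al[, 4])
    gp1 <- as.integer(gm1)
    gp2 <- as.integer(ifelse(mz, gm1, gm2))
    names(gp1) <- names(gp2) <- pairs$pair_id
    G[, s] <- ifelse(ind$twin == 1, gp1[ind$pair_id], gp2[ind$pair_id])
  }
  G
}

#' Inject an additive cis-SNP effect into a protein row
#'
#' Adds `beta * (genotype - mean)` to the target protein with `beta` chosen
#' so the SNP explains the requested fraction `pve` of the protein's total
#' variance, while the pre-existing variation is rescaled by
#' `sqrt(1 - pve)` so the total variance is unchanged.
#'
#' @param proteins Protein matrix (proteins x samples) as returned by
#'   [simulate_protein_levels()].
#' @param genotypes Genotype matrix from [simulate_genotypes()].
#' @param spec A single-row [genotype_spec()]; `spec$gene` selects the
#'   protein row and `spec$snp_id` the genotype column.
#' @param cohort The `twin_cohort` mapping samples to individuals.
#' @return The modified protein matrix.
#' @export
inject_pqtl_effect <- function(proteins, genotypes, spec, cohort) {
  spec <- as.data.frame(spec)
  stopifnot(nrow(spec) == 1)
  if (spec$pve >= 1) stop("pve must be < 1")
  if (spec$pve == 0) return(proteins)
  if (!spec$gene %in% rownames(proteins))
    stop("target protein ", spec$gene, " not present")
  g <- genotypes[cohort$individual_id, spec$snp_id]
  gc <- g - mean(g)
  vg <- stats::var(gc)
  if (vg == 0) stop("monomorphic SNP cannot carry an effect")
  y <- proteins[spec$gene, ]
  vy <- stats::var(y)
  beta <- sqrt(spec$pve * vy / vg)
  proteins[spec$gene, ] <- mean(y) + sqrt(1 - spec$pve) * (y - mean(y)) +
    beta * gc
  proteins
}

#' Build a peptide map for a protein panel
#'
#' Describes the peptide evidence layer to simulate on top of protein
#' values: each protein gets `n_peptides` peptides with fixed log10
#' abundance offsets, iid measurement noise, and a logistic
#' missing-not-at-random model in which low-abundance measurements are more
#' likely to be missing.  A fraction of peptides can be flagged
#' non-proteotypic (shared between two proteins), which downstream
#' filtering discards.
#'
#' @param proteins Character vector of protein ids.
#' @param n_peptides Peptides per protein (recycled).
#' @param offset_sd SD of the fixed per-peptide abundance offsets (log10).
#' @param noise_sd SD of peptide-level measurement noise (log10).
#' @param miss_intercept,miss_slope Logistic missingness parameters:
#'   `P(missing) = plogis(miss_intercept + miss_slope * value)`.  The
#'   defaults give roughly 10% missing cells on the default cohort, with
#'   missingness concentrated at low abundance.
#' @param shared_fraction Fraction of peptides flagged non-proteotypic.
#' @param seed Integer seed (fixes offsets and shared flags).
#' @return A `peptide_map` data.frame: `peptide`, `protein`, `offset`,
#'   `proteotypic`, with the noise/missingness parameters as attributes.
#' @export
peptide_map <- function(proteins, n_peptides = 4, offset_sd = 0.5,
                        noise_sd = 0.15, miss_intercept = -3.13,
                        miss_slope = -1.5, shared_fraction = 0.05,
                        seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng$restore())
  npep <- rep_len(n_peptides, length(proteins))
  prot <- rep(proteins, npep)
  pep <- unlist(lapply(seq_along(proteins), function(i)
    sprintf("%s_pep%d", proteins[i], seq_len(npep[i]))))
  out <- data.frame(
    peptide = pep, protein = prot,
    offset = stats::rnorm(length(pep), 0, offset_sd),
    proteotypic = stats::runif(length(pep)) >= shared_fraction,
    stringsAsFactors = FALSE
  )
  attr(out, "noise_sd") <- noise_sd
  attr(out, "miss_intercept") <- miss_intercept
  attr(out, "miss_slope") <- miss_slope
  class(out) <- c("peptide_map", "data.frame")
  out
}

#' Simulate peptide-level intensities from protein values
#'
#' Each peptide value is its protein's value plus the peptide's fixed
#' abundance offset plus iid Gaussian noise; cells are then set missing
#' with probability `plogis(miss_intercept + miss_slope * value)`, so low
#' abundance censors preferentially (the usual behaviour of
#' intensity-dependent peptide detection).
#'
#' @param proteins Protein matrix (proteins x samples).
#' @param map A [peptide_map()].
#' @param seed Integer seed.
#' @param missingness Logical; turn the missingness model off to obtain a
#'   complete matrix.
#' @return A `peptide_matrix`: list with `values` (peptides x samples; NA
#'   where missing), `missing` (logical matrix), `truth` (pre-censoring
#'   values) and `mapping` (the map).
#' @export
simulate_peptides <- function(proteins, map, seed = 1L, missingness = TRUE) {
  stopifnot(inherits(map, "peptide_map"),
            all(map$protein %in% rownames(proteins)))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  noise_sd <- attr(map, "noise_sd")
  vals <- proteins[map$protein, , drop = FALSE] + map$offset
  if (noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd), nrow(vals))
  rownames(vals) <- map$peptide
  miss <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  if (missingness) {
    pmiss <- stats::plogis(attr(map, "miss_intercept") +
                             attr(map, "miss_slope") * vals)
    miss <- matrix(stats::runif(length(vals)) < pmiss, nrow(vals),
                   dimnames = dimnames(vals))
  }
  out <- vals
  out[miss] <- NA_real_
  structure(list(values = out, missing = miss, truth = vals, mapping = map),
            class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf("peptide matrix: %d peptides x %d samples, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$missing)))
  invisible(x)
}

#' Simulate a cis-SNP panel with annotation for a gene set
#'
#' Places `n_per_gene` SNPs per gene uniformly within `spread` base pairs
#' of the gene's transcription start site (so a 1-kb cis window excludes
#' some of them), with minor-allele frequencies drawn uniformly from
#' `maf_range`.  Genes are laid out 1 Mb apart on a single synthetic
#' chromosome.
#'
#' @param genes Character vector of gene ids.
#' @param n_per_gene SNPs per gene (recycled).
#' @param spread Maximum |offset| from the TSS in bp (default 1500).
#' @param maf_range Range of simulated minor-allele frequencies.
#' @param seed Integer seed.
#' @return List with `specs` (a `genotype_spec` data.frame, `pve = 0`),
#'   `snp_ann` (`snp_id`, `chrom`, `pos`) and `tss` (`gene`, `chrom`,
#'   `tss`).
#' @export
simulate_cis_snps <- function(genes, n_per_gene = 5, spread = 1500,
                              maf_range = c(0.05, 0.5), seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng$restore())
  tss <- data.frame(gene = genes, chrom = "chr1",
                    tss = 1e6 * seq_along(genes), stringsAsFactors = FALSE)
  nn <- rep_len(n_per_gene, length(genes))
  rows <- lapply(seq_along(genes), function(i) {
    off <- as.integer(round(stats::runif(nn[i], -spread, spread)))
    data.frame(
      snp_id = sprintf("%s_snp%d", genes[i], seq_len(nn[i])),
      gene = genes[i], offset = off,
      maf = stats::runif(nn[i], maf_range[1], maf_range[2]),
      pve = 0, stringsAsFactors = FALSE)
  })
  specs <- do.call(rbind, rows)
  class(specs) <- c("genotype_spec", "data.frame")
  snp_ann <- data.frame(snp_id = specs$snp_id, chrom = "chr1",
                        pos = tss$tss[match(specs$gene, tss$gene)] +
                          specs$offset,
                        stringsAsFactors = FALSE)
  list(specs = specs, snp_ann = snp_ann, tss = tss)
}
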