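# TSV interchange: analyte x sample matrices with "#"-prefixed header
# comments (seed, stage), first column = analyte id, header row = sample ids.

#' Write an analyte matrix as annotated TSV
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param comments Character vector written as leading `# ` comment lines
#'   (use to record the generating seed and stage).
#' @param mask Optional logical matrix (same shape) written alongside as
#'   `<path>.mask.tsv` (TRUE = missing/imputed cell).
#' @export
write_matrix_tsv <- function(x, path, comments = character(), mask = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  writeLines(paste(c("analyte", colnames(x)), collapse = "\t"), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = TRUE)
  if (!is.null(mask)) {
    write_matrix_tsv(1 * mask, paste0(path, ".mask.tsv"),
                     comments = "missingness mask (1 = missing)")
  }
  invisible(path)
}

#' Read an annotated analyte TSV matrix
#'
#' @param path File written by [write_matrix_tsv()].
#' @return Numeric matrix; header comments are returned in attribute
#'   `"comments"`.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  cm <- sub("^# ?", "", lines[startsWith(lines, "#")])
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != length(header)))
    stop("ragged rows at line(s): ",
         paste(which(lens != length(header)) + sum(startsWith(lines, "#")) + 1,
               collapse = ", "))
  ids <- vapply(rows, `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicated analyte id: ", ids[duplicated(ids)][1])
  if (anyDuplicated(header[-1]))
    stop("duplicated sample id: ", header[-1][duplicated(header[-1])][1])
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header) - 1)))
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = length(rows))
  bad <- which(is.na(m) & !grepl("^(NA|nan)?$", do.call(
    rbind, lapply(rows, `[`, -1))), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell at data line ", bad[1, 1], ", column ",
         bad[1, 2] + 1)
  dimnames(m) <- list(ids, header[-1])
  attr(m, "comments") <- cm
  m
}

#' Write / read a cohort frame as TSV
#'
#' @param cohort A `twin_cohort`.
#' @param path File path.
#' @param comments Leading comment lines.
#' @export
write_cohort_tsv <- function(cohort, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  utils::write.table(as.data.frame(cohort), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out$plate <- factor(out$plate)
  rownames(out) <- out$sample_id
  class(out) <- c("twin_cohort", "data.frame")
  out
}

#' Write genotypes as a minimal VCF 4.2
#'
#' Emits a sites-by-samples VCF with GT as the only FORMAT field, suitable
#' for interchange with standard tooling.  Additive genotypes 0/1/2 become
#' `0/0`, `0/1`, `1/1`.
#'
#' @param genotypes Integer matrix, individuals x SNPs.
#' @param snp_ann Data.frame `snp_id`, `chrom`, `pos`.
#' @param path Output path (plain text).
#' @param comments Extra `##`-style header comment values.
#' @export
write_vcf <- function(genotypes, snp_ann, path, comments = character()) {
  stopifnot(all(colnames(genotypes) %in% snp_ann$snp_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (cm in comments) writeLines(paste0("##", cm), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes)),
                   collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    ann <- snp_ann[snp_ann$snp_id == colnames(genotypes)[j], ]
    writeLines(paste(c(ann$chrom, ann$pos, ann$snp_id, "A", "G", ".",
                       "PASS", ".", "GT",
                       gt_code[genotypes[, j] + 1]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into an additive genotype matrix
#'
#' Uses vcfR when available; otherwise parses the GT field directly
#' (sufficient for the minimal GT-only files written by [write_vcf()]).
#'
#' @param path VCF path.
#' @return List with `genotypes` (individuals x SNPs additive matrix) and
#'   `snp_ann` (`snp_id`, `chrom`, `pos`).
#' @export
read_vcf_genotypes <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    add <- matrix(vapply(strsplit(gt, "[/|]"), function(a)
      sum(as.integer(a)), integer(1)), nrow(gt), dimnames = dimnames(gt))
    ann <- data.frame(snp_id = vcfR::getID(v), chrom = vcfR::getCHROM(v),
                      pos = vcfR::getPOS(v), stringsAsFactors = FALSE)
    return(list(genotypes = t(add), snp_ann = ann))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:9)]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ann <- data.frame(
    snp_id = vapply(rows, `[`, character(1), 3),
    chrom = vapply(rows, `[`, character(1), 1),
    pos = as.integer(vapply(rows, `[`, character(1), 2)),
    stringsAsFactors = FALSE)
  G <- t(vapply(rows, function(r) {
    gt <- sub(":.*", "", r[-(1:9)])
    vapply(strsplit(gt, "[/|]"), function(a) sum(as.integer(a)), integer(1))
  }, integer(length(samples))))
  G <- matrix(G, nrow = length(rows),
              dimnames = list(ann$snp_id, samples))
  list(genotypes = t(G), snp_ann = ann)
}

#' Write / read a BED-like TSS / SNP annotation TSV
#'
#' Four columns: `chrom`, `pos`, `snp_id`, `gene` (1-based inclusive
#' coordinates).
#'
#' @param snp_ann Data.frame with those columns (the `gene` column is
#'   optional and filled with `NA` when absent).
#' @param path File path.
#' @export
write_snp_bed <- function(snp_ann, path) {
  df <- data.frame(chrom = snp_ann$chrom, pos = snp_ann$pos,
                   snp_id = snp_ann$snp_id,
                   gene = if ("gene" %in% names(snp_ann)) snp_ann$gene
                   else NA_character_)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_bed
#' @export
read_snp_bed <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
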