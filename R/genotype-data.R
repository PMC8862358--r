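#' Genotype data container
#'
#' Holds an ordered table of bi-allelic sites together with per-sample
#' genotype matrices: alt-allele dosage (`gt`, values 0/1/2 or `NA` for a
#' missing call), read depth (`dp`), genotype quality (`gq`) and the
#' phred-scaled genotype likelihood triple (`pl`, a list of three matrices
#' `RR`, `RA`, `AA`). All matrices are sites x samples and share dimensions.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; a `vtype` column (`SNP`/`INS`/`DEL`) is derived if absent.
#' @param samples character vector of sample identifiers (column order of the
#'   matrices).
#' @param gt integer matrix of alt-allele dosages; `NA` marks a missing call.
#' @param dp,gq optional integer matrices of read depth / genotype quality.
#' @param pl optional list of three numeric matrices `RR`, `RA`, `AA`.
#' @param chrom_lengths optional named vector of chromosome lengths (bp),
#'   carried along for window tiling and VCF headers.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(sites, samples, gt, dp = NULL, gq = NULL, pl = NULL,
                          chrom_lengths = NULL) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (is.null(sites$vtype)) sites$vtype <- variant_type(sites$ref, sites$alt)
  if (any(sites$pos < 1)) stop("site positions must be >= 1")
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(sites) || ncol(gt) != length(samples))
    stop("gt must be a sites x samples matrix")
  o <- order(sites$chrom, sites$pos)
  reord <- function(m) if (is.null(m)) NULL else as.matrix(m)[o, , drop = FALSE]
  x <- list(
    sites = sites[o, , drop = FALSE],
    samples = as.character(samples),
    gt = reord(gt),
    dp = reord(dp),
    gq = reord(gq),
    pl = if (is.null(pl)) NULL else lapply(pl, function(m) as.matrix(m)[o, , drop = FALSE]),
    chrom_lengths = chrom_lengths,
    log = list()
  )
  rownames(x$sites) <- NULL
  dimnames(x$gt) <- list(NULL, x$samples)
  class(x) <- "genotype_data"
  x
}

#' Classify bi-allelic variants from their alleles
#'
#' @param ref,alt allele strings.
#' @return character vector: `SNP`, `INS` or `DEL`.
#' @export
variant_type <- function(ref, alt) {
  d <- nchar(alt) - nchar(ref)
  ifelse(d == 0L, "SNP", ifelse(d > 0L, "INS", "DEL"))
}

#' Length of the insertion/deletion at each site (0 for SNPs)
#' @param g a `genotype_data` object.
#' @return integer vector of |len(alt) - len(ref)|.
#' @export
indel_length <- function(g) {
  abs(nchar(g$sites$alt) - nchar(g$sites$ref))
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d sites x %d samples\n", nrow(x$sites), length(x$samples)))
  tab <- table(x$sites$vtype)
  cat("  variant types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  fields: gt%s%s%s\n",
              if (!is.null(x$dp)) ", dp" else "",
              if (!is.null(x$gq)) ", gq" else "",
              if (!is.null(x$pl)) ", pl" else ""))
  if (length(x$log)) cat(sprintf("  filter log entries: %d\n", length(x$log)))
  invisible(x)
}

#' Subset a genotype_data object to a set of site rows
#' @param g a `genotype_data` object.
#' @param keep logical or integer index over sites.
#' @return the subset `genotype_data`.
#' @export
subset_sites <- function(g, keep) {
  g$sites <- g$sites[keep, , drop = FALSE]
  rownames(g$sites) <- NULL
  g$gt <- g$gt[keep, , drop = FALSE]
  if (!is.null(g$dp)) g$dp <- g$dp[keep, , drop = FALSE]
  if (!is.null(g$gq)) g$gq <- g$gq[keep, , drop = FALSE]
  if (!is.null(g$pl)) g$pl <- lapply(g$pl, function(m) m[keep, , drop = FALSE])
  g
}

log_step <- function(g, name, ...) {
  g$log[[length(g$log) + 1L]] <- c(list(step = name), list(...))
  g
}

#' Write the accumulated filter log as machine-readable JSON
#' @param g a `genotype_data` object.
#' @param path output file.
#' @export
write_filter_report <- function(g, path) {
  jsonlite::write_json(g$log, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Sample-to-line assignment
#'
#' @param assignment named character vector mapping sample identifier to line
#'   label, or a two-column data.frame (sample, line).
#' @param pseudo_lines named list of character vectors; each entry defines a
#'   pooled pseudo-line in terms of primary line labels (e.g.
#'   `list(FERT = c("DUK", "DUC"))`).
#' @return An object of class `line_map`.
#' @export
line_map <- function(assignment, pseudo_lines = list()) {
  if (is.data.frame(assignment)) {
    assignment <- setNames(as.character(assignment[[2]]), as.character(assignment[[1]]))
  }
  stopifnot(!is.null(names(assignment)), !anyDuplicated(names(assignment)))
  lines <- unique(unname(assignment))
  for (pl in names(pseudo_lines)) {
    miss <- setdiff(pseudo_lines[[pl]], lines)
    if (length(miss)) stop("pseudo-line ", pl, " references unknown lines: ",
                           paste(miss, collapse = ", "))
  }
  structure(list(assignment = assignment, pseudo_lines = pseudo_lines,
                 lines = lines), class = "line_map")
}

#' Read a sample-to-line map from a two-column TSV
#' @param path TSV file with columns sample, line (no header required; a
#'   header line `sample<TAB>line` is tolerated).
#' @param pseudo_lines passed on to [line_map()].
#' @export
read_line_map <- function(path, pseudo_lines = list()) {
  tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("sample", "line"))
  if (nrow(tab) && identical(tolower(tab$sample[1]), "sample")) tab <- tab[-1, ]
  line_map(tab, pseudo_lines = pseudo_lines)
}

#' Write a sample-to-line map as TSV
#' @param lm a `line_map`.
#' @param path output file.
#' @export
write_line_map <- function(lm, path) {
  write.table(data.frame(sample = names(lm$assignment), line = unname(lm$assignment)),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.line_map <- function(x, ...) {
  tab <- table(x$assignment)
  cat("line_map:", length(x$assignment), "samples in", length(tab), "lines\n")
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (length(x$pseudo_lines))
    cat("  pseudo-lines:", paste(sprintf("%s={%s}", names(x$pseudo_lines),
        vapply(x$pseudo_lines, paste, "", collapse = ",")), collapse = "; "), "\n")
  invisible(x)
}

#' Samples belonging to a (pseudo-)line
#' @param lm a `line_map`.
#' @param line a primary line label or the name of a pseudo-line.
#' @return character vector of sample names.
#' @export
line_samples <- function(lm, line) {
  labs <- if (line %in% names(lm$pseudo_lines)) lm$pseudo_lines[[line]] else line
  unknown <- setdiff(labs, lm$lines)
  if (length(unknown)) stop("unknown line label(s): ", paste(unknown, collapse = ", "))
  names(lm$assignment)[lm$assignment %in% labs]
}
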