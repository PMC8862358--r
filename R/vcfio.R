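#' Read a multi-sample VCF into a genotype_data object
#'
#' Parses a VCF v4.2 file (plain or bgzipped) keeping only bi-allelic records;
#' multi-allelic records are skipped and counted in the filter log. GT is
#' required; DP, GQ and PL are read when present in the FORMAT field.
#'
#' @param path VCF file.
#' @param line_map_path optional two-column TSV (sample, line); when given,
#'   the map must cover every sample in the VCF.
#' @param pseudo_lines passed to [line_map()] when `line_map_path` is given.
#' @return A `genotype_data` object; if `line_map_path` was supplied the
#'   corresponding `line_map` is attached as `$line_map`.
#' @export
read_vcf <- function(path, line_map_path = NULL, pseudo_lines = list()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records")
  fmt <- strsplit(vcf@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]]
  if (!"GT" %in% fmt) stop("VCF FORMAT lacks the GT field")

  multi <- grepl(",", fix$ALT, fixed = TRUE) | fix$ALT %in% c(".", "*")
  n_multi <- sum(multi)

  gt_chr <- vcfR::extract.gt(vcf, "GT")
  samples <- colnames(gt_chr)
  gt <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr))
  gt[gt_chr %in% c("0/0", "0|0")] <- 0L
  gt[gt_chr %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_chr %in% c("1/1", "1|1")] <- 2L

  dp <- if ("DP" %in% fmt) vcfR::extract.gt(vcf, "DP", as.numeric = TRUE) else NULL
  gq <- if ("GQ" %in% fmt) vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE) else NULL
  pl <- NULL
  if ("PL" %in% fmt) {
    plc <- vcfR::extract.gt(vcf, "PL")
    pl <- list(RR = vcfR::masplit(plc, record = 1, sort = FALSE),
               RA = vcfR::masplit(plc, record = 2, sort = FALSE),
               AA = vcfR::masplit(plc, record = 3, sort = FALSE))
  }

  keep <- !multi
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)[keep, ]
  sub <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  g <- genotype_data(sites, samples, sub(gt), dp = sub(dp), gq = sub(gq),
                     pl = if (is.null(pl)) NULL else lapply(pl, function(m) m[keep, , drop = FALSE]),
                     chrom_lengths = vcf_contig_lengths(vcf))
  g <- log_step(g, "read_vcf", path = path, n_records = nrow(fix),
                n_multiallelic_skipped = n_multi, n_sites = nrow(g$sites))
  if (!is.null(line_map_path)) {
    lm <- read_line_map(line_map_path, pseudo_lines = pseudo_lines)
    unknown <- setdiff(samples, names(lm$assignment))
    if (length(unknown)) stop("samples missing from line map: ",
                              paste(unknown, collapse = ", "))
    g$line_map <- lm
  }
  g
}

vcf_contig_lengths <- function(vcf) {
  meta <- vcf@meta
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (!length(ctg)) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
  if (all(is.na(lens))) return(NULL)
  setNames(lens, ids)
}

#' Write a genotype_data object as a VCF v4.2 file
#'
#' Emits GT plus whichever of DP/GQ/PL are present. Missing genotype calls are
#' written as `./.`; their DP/GQ/PL values (if stored) are written unchanged,
#' so a read/write cycle preserves all retained fields.
#'
#' @param g a `genotype_data` object.
#' @param path output file path.
#' @export
write_vcf <- function(g, path) {
  fmt <- c("GT", if (!is.null(g$dp)) "DP", if (!is.null(g$gq)) "GQ",
           if (!is.null(g$pl)) "PL")
  hdr <- c("##fileformat=VCFv4.2", "##source=lineselect")
  if (!is.null(g$chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(g$chrom_lengths),
                          as.integer(g$chrom_lengths)))
  hdr <- c(hdr,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(g$dp)) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    if (!is.null(g$gq)) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    if (!is.null(g$pl)) '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$gt + 1L], nrow(g$gt))
  gt_str[is.na(g$gt)] <- "./."
  cells <- gt_str
  if (!is.null(g$dp)) cells <- matrix(paste(cells, as.integer(g$dp), sep = ":"), nrow(cells))
  if (!is.null(g$gq)) cells <- matrix(paste(cells, as.integer(g$gq), sep = ":"), nrow(cells))
  if (!is.null(g$pl))
    cells <- matrix(paste0(cells, ":", as.integer(g$pl$RR), ",",
                           as.integer(g$pl$RA), ",", as.integer(g$pl$AA)),
                    nrow(cells))
  cells <- gsub(":NA", ":.", cells, fixed = TRUE)
  body <- paste(g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt, ".",
                "PASS", ".", paste(fmt, collapse = ":"),
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED interval track
#'
#' @param path BED file (0-based half-open intervals).
#' @param name track name attached as metadata.
#' @return A sorted, merged `GRanges` (1-based, closed intervals as usual for
#'   GRanges).
#' @export
read_bed_track <- function(path, name = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Build an interval track from 0-based half-open coordinates
#'
#' @param chrom,start,end vectors describing intervals in BED convention
#'   (0-based start, exclusive end).
#' @param name track name.
#' @return A sorted, merged `GRanges`.
#' @export
interval_track <- function(chrom, start, end, name = "track") {
  stopifnot(all(start < end))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Genotype-level depth and quality filters
#'
#' Marks individual genotype calls as missing when the supporting read depth
#' is too low (`dp < dp_min`), implausibly high (`dp` above the sample's mean
#' depth plus `dp_sd_mult` standard deviations; mean and sd are computed per
#' sample over its cells with recorded depth, population divisor) or the
#' genotype quality is too low (`gq < gq_min`). Dosage values of surviving
#' calls are untouched. Sites where every sample becomes missing are dropped
#' and counted in the filter log. Because the per-sample depth summaries are
#' computed from recorded depths (which filtering never erases), the filter is
#' idempotent.
#'
#' @param g a `genotype_data` with `dp` and `gq` matrices.
#' @param dp_min minimum depth for a call (default 4).
#' @param dp_sd_mult sample-mean + this many sd defines the maximum allowed
#'   depth (default 3).
#' @param gq_min minimum genotype quality (default 20).
#' @return The filtered `genotype_data`.
#' @export
apply_genotype_filters <- function(g, dp_min = 4, dp_sd_mult = 3, gq_min = 20) {
  if (is.null(g$dp) || is.null(g$gq)) stop("dp and gq are required for genotype filtering")
  pop_sd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    sqrt(mean((x - mean(x))^2))
  }
  mu <- colMeans(g$dp, na.rm = TRUE)
  sdv <- apply(g$dp, 2, pop_sd)
  all_missing_samples <- g$samples[!is.finite(mu)]
  if (length(all_missing_samples))
    warning("samples with no recorded depth: ", paste(all_missing_samples, collapse = ", "))
  dp_max <- mu + dp_sd_mult * sdv
  bad <- is.na(g$dp) | g$dp < dp_min |
    sweep(g$dp, 2, dp_max, ">") |
    is.na(g$gq) | g$gq < gq_min
  bad[is.na(bad)] <- TRUE
  n_masked <- sum(bad & !is.na(g$gt))
  g$gt[bad] <- NA_integer_
  empty <- rowSums(!is.na(g$gt)) == 0L
  g <- subset_sites(g, !empty)
  log_step(g, "apply_genotype_filters", dp_min = dp_min, dp_sd_mult = dp_sd_mult,
           gq_min = gq_min, n_cells_masked = n_masked,
           n_sites_dropped_all_missing = sum(empty),
           all_missing_samples = as.list(all_missing_samples))
}

#' Per-line site support filter
#'
#' Retains sites with a non-missing genotype call in at least `min_support`
#' samples of every primary line; per-line overrides accommodate lines with
#' lower coverage. Optionally (`require_alt = TRUE`) a line additionally has
#' to carry at least one alt allele for the site to count as present there.
#'
#' @param g a `genotype_data`.
#' @param lm a `line_map`.
#' @param min_support default per-line threshold (default 15).
#' @param overrides named numeric vector of per-line thresholds
#'   (default `c(DU6 = 12)`).
#' @param require_alt also require the alt allele to be observed in each line
#'   (default FALSE).
#' @return The filtered `genotype_data`.
#' @export
site_support_filter <- function(g, lm, min_support = 15, overrides = c(DU6 = 12),
                                require_alt = FALSE) {
  keep <- rep(TRUE, nrow(g$sites))
  for (ln in lm$lines) {
    cols <- match(line_samples(lm, ln), g$samples)
    cols <- cols[!is.na(cols)]
    if (!length(cols)) next
    thr <- if (ln %in% names(overrides)) overrides[[ln]] else min_support
    called <- rowSums(!is.na(g$gt[, cols, drop = FALSE]))
    ok <- called >= thr
    if (require_alt)
      ok <- ok & rowSums(g$gt[, cols, drop = FALSE], na.rm = TRUE) >= 1
    keep <- keep & ok
  }
  g <- subset_sites(g, keep)
  log_step(g, "site_support_filter", min_support = min_support,
           overrides = as.list(overrides), require_alt = require_alt,
           n_sites_dropped = sum(!keep), n_sites = nrow(g$sites))
}

#' Remove variants of given types overlapping an interval track
#'
#' A variant's reference footprint is the half-open interval
#' `[pos, pos + L)` where `L` is the INDEL length (a single base for SNPs);
#' variants of the requested types whose footprint overlaps any track
#' interval are removed. The default reproduces the exclusion of INDELs
#' overlapping microsatellites; SNPs are untouched.
#'
#' @param g a `genotype_data`.
#' @param track a `GRanges` (see [read_bed_track()] / [interval_track()]).
#' @param vtypes variant types subject to removal (default INS and DEL).
#' @return The filtered `genotype_data`.
#' @export
exclude_intervals <- function(g, track, vtypes = c("INS", "DEL")) {
  len <- indel_length(g)
  cand <- which(g$sites$vtype %in% vtypes)
  drop <- integer(0)
  if (length(cand)) {
    sr <- GenomicRanges::GRanges(g$sites$chrom[cand],
                                 IRanges::IRanges(g$sites$pos[cand],
                                                  g$sites$pos[cand] +
                                                    pmax(len[cand] - 1L, 0L)))
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(sr, track)))
    drop <- cand[hit]
  }
  keep <- setdiff(seq_len(nrow(g$sites)), drop)
  g <- subset_sites(g, keep)
  log_step(g, "exclude_intervals", track = S4Vectors::metadata(track)$name %||% "track",
           vtypes = as.list(vtypes), n_sites_dropped = length(drop))
}
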