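#' Weir-Cockerham per-site F_ST variance components (two populations)
#'
#' Implements the 1984 variance-component estimator for two populations at a
#' bi-allelic site. Inputs are alt-allele counts `j` over `2 n` chromosomes,
#' diploid sample sizes `n`, and observed heterozygote frequencies `h`. All
#' arguments are vectorized over sites.
#'
#' With r = 2 populations: nbar = (n1+n2)/2, nc = (2 nbar - sum(n_i^2)/(2
#' nbar)), pbar = sum(n_i p_i)/(2 nbar), s2 = sum(n_i (p_i - pbar)^2)/nbar,
#' hbar = sum(n_i h_i)/(2 nbar), and the components
#' a = (nbar/nc) (s2 - (pbar(1-pbar) - s2/2 - hbar/4)/(nbar-1)),
#' b = (nbar/(nbar-1)) (pbar(1-pbar) - s2/2 - (2 nbar - 1)/(4 nbar) hbar),
#' c = hbar/2; fst = a/(a+b+c), `NA` where the denominator is 0 (populations
#' jointly monomorphic).
#'
#' @param j1,n1,h1 alt count, diploid sample size, het frequency in
#'   population 1.
#' @param j2,n2,h2 same for population 2.
#' @return data.frame with columns a, b, c, fst.
#' @export
wc_fst_site <- function(j1, n1, h1, j2, n2, h2) {
  if (any(n1 < 1 | n2 < 1, na.rm = TRUE)) stop("diploid sample sizes must be >= 1")
  p1 <- j1 / (2 * n1)
  p2 <- j2 / (2 * n2)
  r <- 2
  nbar <- (n1 + n2) / r
  if (any(nbar <= 1, na.rm = TRUE)) stop("nbar <= 1: too few samples for the estimator")
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  if (any(nc == 0, na.rm = TRUE)) stop("degenerate sample sizes (nc = 0)")
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(denom == 0, NA_real_, a / denom)
  data.frame(a = a, b = b, c = cc, fst = fst)
}

line_counts_for_fst <- function(g, lm, line) {
  cols <- match(line_samples(lm, line), g$samples)
  cols <- cols[!is.na(cols)]
  gt <- g$gt[, cols, drop = FALSE]
  called <- rowSums(!is.na(gt))
  list(j = rowSums(gt, na.rm = TRUE), n = called,
       h = ifelse(called > 0, rowSums(gt == 1L, na.rm = TRUE) / called, NA))
}

#' Per-site F_ST for one contrast (target line vs reference line)
#'
#' Sites are dropped when either group has fewer than one called sample or
#' the pooled sample is too small for the estimator (nbar <= 1).
#'
#' @param g a `genotype_data` (SNP sites recommended).
#' @param lm a `line_map`.
#' @param target target (pseudo-)line label.
#' @param ref reference line label (default `"FZTDU"`).
#' @param snps_only restrict to SNP sites (default TRUE).
#' @return data.frame: chrom, pos, a, b, c, fst (NA where undefined).
#' @export
fst_sites <- function(g, lm, target, ref = "FZTDU", snps_only = TRUE) {
  if (identical(target, ref)) stop("target and reference must differ")
  if (snps_only) g <- subset_sites(g, g$sites$vtype == "SNP")
  t1 <- line_counts_for_fst(g, lm, target)
  t2 <- line_counts_for_fst(g, lm, ref)
  ok <- t1$n >= 1 & t2$n >= 1 & (t1$n + t2$n) > 2
  res <- data.frame(chrom = g$sites$chrom[ok], pos = g$sites$pos[ok])
  wc <- wc_fst_site(t1$j[ok], t1$n[ok], t1$h[ok], t2$j[ok], t2$n[ok], t2$h[ok])
  cbind(res, wc)
}

#' Multi-locus Weir-Cockerham F_ST (ratio of summed components)
#'
#' The standard genome-wide estimator: sum of `a` components over sites
#' divided by the sum of `a + b + c`.
#'
#' @param site_fst output of [fst_sites()] (or any data.frame with a, b, c).
#' @return a single F_ST value.
#' @export
fst_global <- function(site_fst) {
  sum(site_fst$a, na.rm = TRUE) /
    sum(site_fst$a + site_fst$b + site_fst$c, na.rm = TRUE)
}

#' Windowed mean F_ST
#'
#' Tiles sliding windows from position 1 and averages the per-SNP F_ST values
#' (arithmetic mean, negative estimates included as-is) over the sites with a
#' defined F_ST in each window; windows with fewer than `min_snps` defined
#' sites are omitted.
#'
#' @param site_fst output of [fst_sites()].
#' @param w a [window_spec()].
#' @param chrom_lengths named chromosome lengths; defaults to the maximum
#'   site position per chromosome.
#' @return data.frame: chrom, start, end, n_snps, mean_fst.
#' @export
windowed_fst <- function(site_fst, w = window_spec(), chrom_lengths = NULL) {
  def <- site_fst[!is.na(site_fst$fst), ]
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(site_fst$pos, site_fst$chrom, max)[unique(site_fst$chrom)]
  wins <- tile_windows(chrom_lengths, w)
  site_gr <- GenomicRanges::GRanges(def$chrom, IRanges::IRanges(def$pos, width = 1))
  win_gr <- GenomicRanges::GRanges(wins$chrom, IRanges::IRanges(wins$start, wins$end))
  ov <- GenomicRanges::findOverlaps(site_gr, win_gr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  mean_fst <- tapply(def$fst[qh], sh, mean)
  n_snps <- tapply(rep(1L, length(qh)), sh, sum)
  idx <- as.integer(names(mean_fst))
  wins$n_snps <- 0L
  wins$mean_fst <- NA_real_
  wins$n_snps[idx] <- as.integer(n_snps)
  wins$mean_fst[idx] <- as.numeric(mean_fst)
  out <- wins[wins$n_snps >= w$min_snps, ]
  rownames(out) <- NULL
  out
}

#' z-standardize window F_ST values (X chromosome separately)
#'
#' Window means are transformed to z-scores against the genome-wide window
#' distribution; windows on the X chromosome form their own standardization
#' group because of its different effective population size. The standard
#' deviation uses the population divisor.
#'
#' @param windows output of [windowed_fst()].
#' @param x_chrom chromosome names treated as X (default `c("X", "chrX")`).
#' @param value column to standardize (default `"mean_fst"`).
#' @return `windows` with a `z` column added.
#' @export
zscore_windows <- function(windows, x_chrom = c("X", "chrX"),
                           value = "mean_fst") {
  grp <- windows$chrom %in% x_chrom
  z <- rep(NA_real_, nrow(windows))
  for (gset in list(which(!grp), which(grp))) {
    if (!length(gset)) next
    if (length(gset) < 2) stop("need at least 2 windows per standardization group")
    x <- windows[[value]][gset]
    mu <- mean(x)
    sdv <- sqrt(mean((x - mu)^2))
    if (sdv == 0) stop("zero variance in a standardization group")
    z[gset] <- (x - mu) / sdv
  }
  windows$z <- z
  windows
}

#' Genome-wide mean pairwise F_ST matrix
#'
#' For every pair of lines, computes windowed F_ST and averages the window
#' means (`method = "window_mean"`, mirroring arithmetic-mean windowing), or
#' returns the multi-locus ratio-of-sums estimate (`method =
#' "ratio_of_sums"`).
#'
#' @param g a `genotype_data`.
#' @param lm a `line_map`.
#' @param lines lines to compare (default: primary lines).
#' @param w a [window_spec()] (used by `window_mean`).
#' @param method averaging method.
#' @return symmetric matrix of pairwise F_ST with NA diagonal.
#' @export
genomewide_mean_fst <- function(g, lm, lines = lm$lines, w = window_spec(),
                                method = c("window_mean", "ratio_of_sums")) {
  method <- match.arg(method)
  k <- length(lines)
  m <- matrix(NA_real_, k, k, dimnames = list(lines, lines))
  for (i in seq_len(k - 1)) {
    for (jdx in (i + 1):k) {
      sf <- fst_sites(g, lm, lines[i], ref = lines[jdx])
      val <- if (method == "window_mean") {
        wf <- windowed_fst(sf, w, chrom_lengths = chrom_lengths_or_max(g))
        if (!nrow(wf)) stop("no windows passed min_snps for pair ",
                            lines[i], "-", lines[jdx])
        mean(wf$mean_fst)
      } else {
        fst_global(sf)
      }
      m[i, jdx] <- m[jdx, i] <- val
    }
  }
  m
}

#' Run all line-vs-reference window scans
#'
#' Convenience wrapper computing per-site F_ST, window means and z-scores for
#' each target contrast against a common reference line, including any
#' pseudo-lines.
#'
#' @param g a `genotype_data`.
#' @param lm a `line_map`.
#' @param targets contrast targets (default: all primary lines except the
#'   reference, plus pseudo-lines).
#' @param ref the reference line (default `"FZTDU"`).
#' @param w a [window_spec()].
#' @param x_chrom passed to [zscore_windows()]; skipped if no window needs it.
#' @return named list of window data.frames (one per target).
#' @export
fst_contrasts <- function(g, lm, targets = NULL, ref = "FZTDU",
                          w = window_spec(), x_chrom = c("X", "chrX")) {
  if (is.null(targets))
    targets <- c(setdiff(lm$lines, ref), names(lm$pseudo_lines))
  cl <- chrom_lengths_or_max(g)
  out <- lapply(targets, function(tg) {
    wf <- windowed_fst(fst_sites(g, lm, tg, ref = ref), w, chrom_lengths = cl)
    has_x <- any(wf$chrom %in% x_chrom)
    auto <- sum(!wf$chrom %in% x_chrom)
    if (nrow(wf) >= 2 && (!has_x || sum(wf$chrom %in% x_chrom) >= 2) && auto >= 2)
      wf <- zscore_windows(wf, x_chrom = x_chrom)
    wf
  })
  names(out) <- targets
  out
}

#' Detect regions of distinct genetic differentiation (RDDs)
#'
#' A window qualifies for the target contrast when its mean F_ST is at or
#' above the target's `top_pct` percentile and, in every other contrast where
#' the window exists, at or below that contrast's `bottom_pct` percentile;
#' windows absent from any other contrast are disqualified (conservative).
#' Qualifying windows that overlap or abut are merged into maximal regions.
#' Percentiles use linear interpolation between order statistics.
#'
#' When the target or the other contrasts include overlapping pooled
#' pseudo-lines (e.g. a FERT pseudo-line alongside its member lines), the
#' contrasts sharing samples with the target are excluded from the "all other
#' contrasts" rule.
#'
#' @param contrasts named list of window data.frames (see [fst_contrasts()]).
#' @param target name of the target contrast.
#' @param top_pct upper percentile for the target contrast (default 95).
#' @param bottom_pct lower percentile for the other contrasts (default 10).
#' @param exclude additional contrast names to drop from the "others" rule;
#'   by default pseudo-line/member overlaps with the target are excluded
#'   automatically via `lm`.
#' @param lm optional `line_map` used to derive the automatic exclusions.
#' @return list: `regions` (data.frame chrom, start, end, n_windows,
#'   max_mean_fst), `windows` (the qualifying windows), `thresholds`.
#' @export
detect_rdd <- function(contrasts, target, top_pct = 95, bottom_pct = 10,
                       exclude = NULL, lm = NULL) {
  if (!target %in% names(contrasts)) stop("target contrast not found: ", target)
  others <- setdiff(names(contrasts), c(target, exclude))
  if (!is.null(lm) && length(lm$pseudo_lines)) {
    members <- function(x) if (x %in% names(lm$pseudo_lines)) lm$pseudo_lines[[x]] else x
    tset <- members(target)
    overlap <- vapply(others, function(o) length(intersect(members(o), tset)) > 0, TRUE)
    others <- others[!overlap]
  }
  if (!length(others)) stop("no other contrasts to compare against")
  tw <- contrasts[[target]]
  thr_top <- quantile(tw$mean_fst, top_pct / 100, type = 7, names = FALSE)
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  tkey <- key(tw)
  qual <- tw$mean_fst >= thr_top
  thr_bot <- numeric(0)
  for (o in others) {
    ow <- contrasts[[o]]
    thr <- quantile(ow$mean_fst, bottom_pct / 100, type = 7, names = FALSE)
    thr_bot[o] <- thr
    val <- ow$mean_fst[match(tkey, key(ow))]
    qual <- qual & !is.na(val) & val <= thr
  }
  qw <- tw[qual, , drop = FALSE]
  if (!nrow(qw)) {
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), n_windows = integer(),
                          max_mean_fst = numeric())
  } else {
    gr <- GenomicRanges::GRanges(qw$chrom, IRanges::IRanges(qw$start, qw$end),
                                 fst = qw$mean_fst)
    red <- GenomicRanges::reduce(gr, min.gapwidth = 1L, with.revmap = TRUE)
    rv <- S4Vectors::mcols(red)$revmap
    regions <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(red)),
      start = GenomicRanges::start(red), end = GenomicRanges::end(red),
      n_windows = lengths(rv),
      max_mean_fst = vapply(rv, function(ii) max(qw$mean_fst[ii]), 0))
  }
  list(regions = regions, windows = qw,
       thresholds = list(target = thr_top, others = thr_bot,
                         top_pct = top_pct, bottom_pct = bottom_pct,
                         others_used = others))
}

#' Annotate regions with overlapping genes from a GFF3 file
#'
#' Genes are assigned on any overlap of at least 1 bp, strand-agnostic.
#'
#' @param regions data.frame with chrom, start, end (1-based inclusive).
#' @param gff a GFF3 path or a `GRanges` of gene features.
#' @param feature_type GFF3 feature type to use (default `"gene"`).
#' @return `regions` with a `genes` character column (comma separated gene
#'   identifiers) and `n_genes`.
#' @export
annotate_regions <- function(regions, gff, feature_type = "gene") {
  genes <- if (is.character(gff)) {
    gr <- rtracklayer::import(gff, format = "gff3")
    gr[gr$type == feature_type]
  } else gff
  ids <- if (!is.null(genes$gene_id)) genes$gene_id
    else if (!is.null(genes$ID)) genes$ID
    else if (!is.null(genes$Name)) genes$Name
    else as.character(seq_along(genes))
  if (!nrow(regions)) {
    regions$genes <- character(0); regions$n_genes <- integer(0)
    return(regions)
  }
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  ov <- GenomicRanges::findOverlaps(rgr, genes, ignore.strand = TRUE)
  lst <- split(ids[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
  regions$genes <- ""
  regions$n_genes <- 0L
  idx <- as.integer(names(lst))
  regions$genes[idx] <- vapply(lst, paste, "", collapse = ",")
  regions$n_genes[idx] <- lengths(lst)
  regions
}
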