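#' Caller-specific structural-variant record filters
#'
#' Applies the per-caller quality rules to a table of raw SV records:
#' \itemize{
#'   \item manta: mapping quality >= `mapq_min`, local coverage no more than
#'     `depth_ratio_max` times the chromosome median, genotype quality >=
#'     `gq_min`, read depth >= `depth_min`;
#'   \item whamg: size within `[size_min, size_max]`, read depth >=
#'     `depth_min`, genotype quality >= `gq_min`, cross-chromosomal mapping
#'     fraction <= `cross_chrom_max`;
#'   \item lumpy: supporting evidence `su` >= `su_min`, genotype quality >=
#'     `gq_min`.
#' }
#' Records from unknown callers raise an error. Drop counts per rule are
#' attached as the `"drop_counts"` attribute.
#'
#' @param records data.frame of SV records (columns: sample, line,
#'   coverage_set, caller, svtype, chrom, start, end, length, gt, gq, mapq,
#'   su, depth, depth_ratio, cross_chrom_fraction).
#' @param mapq_min,depth_ratio_max,gq_min,depth_min,size_min,size_max,su_min,cross_chrom_max
#'   rule thresholds (defaults: 30, 3, 20, 5, 50, 2e6, 5, 0.1).
#' @return The surviving records.
#' @export
filter_caller_records <- function(records, mapq_min = 30, depth_ratio_max = 3,
                                  gq_min = 20, depth_min = 5, size_min = 50,
                                  size_max = 2e6, su_min = 5,
                                  cross_chrom_max = 0.1) {
  unknown <- setdiff(unique(records$caller), c("manta", "whamg", "lumpy"))
  if (length(unknown)) stop("unknown caller(s): ", paste(unknown, collapse = ", "))
  need <- function(cols, caller) {
    miss <- cols[!cols %in% names(records)]
    if (length(miss)) stop(caller, " rules need missing field(s): ",
                           paste(miss, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(records))
  drops <- c()
  mark <- function(bad, label) {
    drops[label] <<- sum(bad & keep)
    keep <<- keep & !bad
  }
  m <- records$caller == "manta"
  if (any(m)) {
    need(c("mapq", "depth_ratio", "gq", "depth"), "manta")
    mark(m & records$mapq < mapq_min, "manta_mapq")
    mark(m & records$depth_ratio > depth_ratio_max, "manta_excess_coverage")
    mark(m & records$gq < gq_min, "manta_gq")
    mark(m & records$depth < depth_min, "manta_depth")
  }
  w <- records$caller == "whamg"
  if (any(w)) {
    need(c("length", "depth", "gq", "cross_chrom_fraction"), "whamg")
    mark(w & (records$length < size_min | records$length > size_max), "whamg_size")
    mark(w & records$depth < depth_min, "whamg_depth")
    mark(w & records$gq < gq_min, "whamg_gq")
    mark(w & records$cross_chrom_fraction > cross_chrom_max, "whamg_cross_chrom")
  }
  l <- records$caller == "lumpy"
  if (any(l)) {
    need(c("su", "gq"), "lumpy")
    mark(l & records$su < su_min, "lumpy_su")
    mark(l & records$gq < gq_min, "lumpy_gq")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- drops
  out
}

# union-find clustering of records whose breakpoints both lie within tol
cluster_breakpoints <- function(start, end, tol) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  o <- order(start)
  for (a in seq_len(n - 1)) {
    i <- o[a]
    for (b in (a + 1):n) {
      k <- o[b]
      if (start[k] - start[i] > tol) break
      if (abs(end[k] - end[i]) <= tol) {
        ri <- find(i); rk <- find(k)
        if (ri != rk) parent[rk] <- ri
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Consensus merge of filtered SV records across callers
#'
#' Within each line, coverage set, SV type and chromosome, records cluster
#' when both breakpoints lie within `breakpoint_tol`; clusters supported by
#' at least `min_callers` distinct callers become consensus SVs with median
#' breakpoints. Clustering is transitive (connected components), so the
#' result does not depend on input order.
#'
#' @param records filtered SV records.
#' @param breakpoint_tol breakpoint tolerance in bp (default 1000).
#' @param min_callers minimum distinct supporting callers (default 2).
#' @param exclude_types SV types parsed but left out of the consensus output
#'   (default insertions, which rarely reach sample-support thresholds).
#' @return data.frame of consensus SVs: line, coverage_set, svtype, chrom,
#'   start, end, n_callers, callers, n_samples, samples, hom_samples.
#' @export
consensus_merge <- function(records, breakpoint_tol = 1000, min_callers = 2,
                            exclude_types = "INS") {
  records <- records[!records$svtype %in% exclude_types, , drop = FALSE]
  if (!nrow(records)) return(empty_consensus())
  grp <- interaction(records$line, records$coverage_set, records$svtype,
                     records$chrom, drop = TRUE)
  out <- list()
  for (gname in levels(grp)) {
    rr <- records[grp == gname, , drop = FALSE]
    cl <- cluster_breakpoints(rr$start, rr$end, breakpoint_tol)
    for (ci in unique(cl)) {
      mem <- rr[cl == ci, , drop = FALSE]
      callers <- sort(unique(mem$caller))
      if (length(callers) < min_callers) next
      smp <- sort(unique(mem$sample))
      hom <- sort(unique(mem$sample[mem$gt == "hom"]))
      out[[length(out) + 1L]] <- data.frame(
        line = mem$line[1], coverage_set = mem$coverage_set[1],
        svtype = mem$svtype[1], chrom = mem$chrom[1],
        start = round(median(mem$start)), end = round(median(mem$end)),
        n_callers = length(callers), callers = paste(callers, collapse = ","),
        n_samples = length(smp), samples = paste(smp, collapse = ","),
        hom_samples = paste(hom, collapse = ","))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_consensus()
  rownames(res) <- NULL
  res
}

empty_consensus <- function() {
  data.frame(line = character(), coverage_set = character(),
             svtype = character(), chrom = character(), start = integer(),
             end = integer(), n_callers = integer(), callers = character(),
             n_samples = integer(), samples = character(),
             hom_samples = character())
}

#' Minimum sample-support filter for consensus SVs
#'
#' @param consensus output of [consensus_merge()].
#' @param min_samples minimum number of distinct carrier samples (default 10).
#' @return The surviving consensus SVs.
#' @export
sample_support_filter <- function(consensus, min_samples = 10) {
  out <- consensus[consensus$n_samples >= min_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of the high- and low-coverage consensus sets
#'
#' Matching SVs (same line, type and chromosome, both breakpoints within
#' `breakpoint_tol`) are deduplicated into one record keeping the
#' high-coverage coordinates, pooled carrier samples and a provenance label;
#' unmatched SVs from either set are carried over.
#'
#' @param high_set,low_set consensus SV data.frames.
#' @param breakpoint_tol breakpoint tolerance in bp (default 1000).
#' @return data.frame with an additional `coverage_sets` provenance column.
#' @export
union_coverage_sets <- function(high_set, low_set, breakpoint_tol = 1000) {
  merge_samples <- function(a, b) {
    paste(sort(unique(c(strsplit(a, ",")[[1]], strsplit(b, ",")[[1]]))),
          collapse = ",")
  }
  high_set$coverage_sets <- rep("high", nrow(high_set))
  low_set$coverage_sets <- rep("low", nrow(low_set))
  if (!nrow(high_set)) return(low_set)
  used <- rep(FALSE, nrow(low_set))
  for (i in seq_len(nrow(high_set))) {
    cand <- which(!used &
                    low_set$line == high_set$line[i] &
                    low_set$svtype == high_set$svtype[i] &
                    low_set$chrom == high_set$chrom[i] &
                    abs(low_set$start - high_set$start[i]) <= breakpoint_tol &
                    abs(low_set$end - high_set$end[i]) <= breakpoint_tol)
    if (length(cand)) {
      k <- cand[1]
      used[k] <- TRUE
      high_set$samples[i] <- merge_samples(high_set$samples[i], low_set$samples[k])
      high_set$hom_samples[i] <- merge_samples(high_set$hom_samples[i],
                                               low_set$hom_samples[k])
      high_set$n_samples[i] <- length(strsplit(high_set$samples[i], ",")[[1]])
      high_set$coverage_sets[i] <- "high,low"
    }
  }
  out <- rbind(high_set, low_set[!used, , drop = FALSE])
  o <- order(out$line, out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask, classify and annotate the final per-line SV sets
#'
#' SVs overlapping any mask interval (assembly gaps, excessive-coverage
#' regions) are removed before classification. An SV is line-specific when no
#' other line carries a tolerance-matched SV of the same type; it is fixed
#' when every genotyped sample of its line is a homozygous carrier. Genic SVs
#' overlap at least 1 bp of a gene interval.
#'
#' @param line_sets data.frame of per-line SVs (output of
#'   [union_coverage_sets()], all lines combined).
#' @param masks list of `GRanges` masks (may be empty).
#' @param genes optional `GRanges` of gene intervals.
#' @param lm a `line_map` (used for per-line sample totals).
#' @param breakpoint_tol cross-line matching tolerance in bp (default 1000).
#' @return `line_sets` with columns `line_specific`, `fixed`, `genic` added
#'   (masked SVs removed).
#' @export
classify_and_mask <- function(line_sets, masks = list(), genes = NULL, lm,
                              breakpoint_tol = 1000) {
  if (!nrow(line_sets)) {
    line_sets$line_specific <- logical(0)
    line_sets$fixed <- logical(0)
    line_sets$genic <- logical(0)
    return(line_sets)
  }
  gr <- GenomicRanges::GRanges(line_sets$chrom,
                               IRanges::IRanges(line_sets$start, line_sets$end))
  drop <- rep(FALSE, nrow(line_sets))
  for (mk in masks) {
    hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, mk))
    drop[unique(hit)] <- TRUE
  }
  x <- line_sets[!drop, , drop = FALSE]
  gr <- gr[!drop]
  n <- nrow(x)
  x$line_specific <- vapply(seq_len(n), function(i) {
    !any(x$line != x$line[i] & x$svtype == x$svtype[i] & x$chrom == x$chrom[i] &
           abs(x$start - x$start[i]) <= breakpoint_tol &
           abs(x$end - x$end[i]) <= breakpoint_tol)
  }, TRUE)
  line_total <- table(lm$assignment)
  x$fixed <- vapply(seq_len(n), function(i) {
    smp <- strsplit(x$samples[i], ",")[[1]]
    hom <- strsplit(x$hom_samples[i], ",")[[1]]
    hom <- hom[nzchar(hom)]
    length(smp) == line_total[[x$line[i]]] && setequal(smp, hom)
  }, TRUE)
  x$genic <- FALSE
  if (!is.null(genes) && length(genes)) {
    hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, genes,
                                                            ignore.strand = TRUE))
    x$genic[unique(hit)] <- TRUE
  }
  rownames(x) <- NULL
  x
}

#' Per-line SV summary table
#'
#' Counts total SVs and line-specific genic SVs by type for each line,
#' mirroring the layout of a final SV summary table.
#'
#' @param classified output of [classify_and_mask()].
#' @param types SV types to tabulate (default DEL, DUP, INV).
#' @return data.frame with one row per line.
#' @export
sv_summary_table <- function(classified, types = c("DEL", "DUP", "INV")) {
  lines <- unique(classified$line)
  out <- lapply(lines, function(ln) {
    d <- classified[classified$line == ln, ]
    tot <- vapply(types, function(tp) sum(d$svtype == tp), 0L)
    lsg <- vapply(types, function(tp)
      sum(d$svtype == tp & d$line_specific & d$genic), 0L)
    df <- data.frame(line = ln)
    for (tp in types) df[[paste0("total_", tp)]] <- tot[[tp]]
    df$total <- sum(tot)
    for (tp in types) df[[paste0("ls_genic_", tp)]] <- lsg[[tp]]
    df$ls_genic_total <- sum(lsg)
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full SV consensus pipeline
#'
#' filter -> per-coverage-set consensus merge -> sample support -> union of
#' coverage sets -> mask/classify, with the stage order enforced.
#'
#' @param records raw caller records (all lines, both coverage sets).
#' @param lm a `line_map`.
#' @param masks,genes see [classify_and_mask()].
#' @param breakpoint_tol,min_callers,min_samples stage thresholds.
#' @param ... further arguments to [filter_caller_records()].
#' @return list with each stage's output and the final `classified` table.
#' @export
sv_pipeline <- function(records, lm, masks = list(), genes = NULL,
                        breakpoint_tol = 1000, min_callers = 2,
                        min_samples = 10, ...) {
  filtered <- filter_caller_records(records, ...)
  cons <- consensus_merge(filtered, breakpoint_tol = breakpoint_tol,
                          min_callers = min_callers)
  supported <- sample_support_filter(cons, min_samples = min_samples)
  high <- supported[supported$coverage_set == "high", , drop = FALSE]
  low <- supported[supported$coverage_set == "low", , drop = FALSE]
  unioned <- union_coverage_sets(high, low, breakpoint_tol = breakpoint_tol)
  classified <- classify_and_mask(unioned, masks = masks, genes = genes,
                                  lm = lm, breakpoint_tol = breakpoint_tol)
  list(filtered = filtered, consensus = cons, supported = supported,
       unioned = unioned, classified = classified,
       summary = sv_summary_table(classified))
}
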