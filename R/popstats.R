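#' Sliding-window specification
#'
#' @param size window size in bp (default 50 kb).
#' @param step window step in bp (default 25 kb).
#' @param min_snps minimum number of usable SNPs for a window to be emitted
#'   (default 10; window statistics with fewer informative sites are
#'   suppressed).
#' @return A `window_spec` list.
#' @export
window_spec <- function(size = 50000, step = 25000, min_snps = 10) {
  stopifnot(step <= size, min_snps >= 1)
  structure(list(size = size, step = step, min_snps = min_snps),
            class = "window_spec")
}

#' Tile sliding windows over chromosomes
#'
#' Windows start at position 1 and advance by `step`; coordinates are 1-based
#' inclusive.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param w a [window_spec()].
#' @return data.frame: chrom, start, end.
#' @export
tile_windows <- function(chrom_lengths, w) {
  out <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, max(1, chrom_lengths[[ch]]), by = w$step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + w$size - 1, chrom_lengths[[ch]]))
  })
  do.call(rbind, out)
}

chrom_lengths_or_max <- function(g) {
  if (!is.null(g$chrom_lengths)) return(g$chrom_lengths)
  tapply(g$sites$pos, g$sites$chrom, max)[unique(g$sites$chrom)]
}

#' Per-line allele counts and frequencies
#'
#' For every (pseudo-)line and site, counts the alt alleles `j` among the
#' `n` called chromosomes (twice the non-missing genotypes) and the observed
#' heterozygote frequency. Pseudo-lines pool the samples of their member
#' lines. Frequencies are `NA` where a line has no called genotype.
#'
#' @param g a filtered `genotype_data`.
#' @param lm a `line_map`.
#' @param include_pseudo also compute the configured pseudo-lines.
#' @return A `line_af` object: list of matrices `j`, `n`, `p`, `het`
#'   (sites x lines) plus the site table.
#' @export
line_allele_frequencies <- function(g, lm, include_pseudo = TRUE) {
  labs <- c(lm$lines, if (include_pseudo) names(lm$pseudo_lines))
  j <- n <- het <- matrix(NA_real_, nrow(g$sites), length(labs),
                          dimnames = list(NULL, labs))
  for (ln in labs) {
    cols <- match(line_samples(lm, ln), g$samples)
    cols <- cols[!is.na(cols)]
    gt <- g$gt[, cols, drop = FALSE]
    called <- rowSums(!is.na(gt))
    j[, ln] <- rowSums(gt, na.rm = TRUE)
    n[, ln] <- 2 * called
    het[, ln] <- ifelse(called > 0, rowSums(gt == 1L, na.rm = TRUE) / called, NA)
  }
  p <- ifelse(n > 0, j / n, NA)
  structure(list(j = j, n = n, p = p, het = het, sites = g$sites,
                 lines = lm$lines, pseudo = if (include_pseudo) names(lm$pseudo_lines) else character(0)),
            class = "line_af")
}

#' Classify sites per line as fixed or polymorphic
#'
#' @param af a `line_af`.
#' @return character matrix (sites x lines) with values `fixed_ref`
#'   (p = 0), `fixed_alt` (p = 1), `polymorphic` (0 < p < 1) and `uncalled`
#'   (no called genotype in the line).
#' @export
classify_sites <- function(af) {
  cls <- matrix("uncalled", nrow(af$p), ncol(af$p), dimnames = dimnames(af$p))
  cls[!is.na(af$p) & af$p == 0] <- "fixed_ref"
  cls[!is.na(af$p) & af$p == 1] <- "fixed_alt"
  cls[!is.na(af$p) & af$p > 0 & af$p < 1] <- "polymorphic"
  cls
}

#' Private and shared alt-allele site sets across lines
#'
#' A site carries the alt allele in a line when at least one alt allele was
#' called there (`j >= 1`). Reports per-line totals, private sites, the
#' intersection over the trait-selected lines only (alt present in every
#' trait line, absent from the control), the all-lines intersection, and the
#' per-line fraction of carried sites also present in the control line.
#'
#' @param af a `line_af`.
#' @param lines lines to consider (default: the primary lines of the map).
#' @param control the control line used for the "shared with control"
#'   fraction (default `"FZTDU"` when present).
#' @return list with `membership` (logical sites x lines matrix), `totals`,
#'   `private`, `trait_only`, `all_lines` and `shared_with_control`.
#' @export
shared_private_sets <- function(af, lines = af$lines,
                                control = intersect("FZTDU", lines)) {
  m <- af$j[, lines, drop = FALSE] >= 1
  m[is.na(m)] <- FALSE
  totals <- colSums(m)
  nshare <- rowSums(m)
  private <- colSums(m & nshare == 1L)
  trait <- setdiff(lines, control)
  trait_only <- if (length(control))
    sum(rowSums(m[, trait, drop = FALSE]) == length(trait) &
          !m[, control, drop = FALSE][, 1]) else NA_integer_
  all_lines <- sum(nshare == length(lines))
  shared_ctrl <- if (length(control)) {
    vapply(lines, function(ln) {
      tot <- sum(m[, ln]); if (tot == 0) return(NA_real_)
      sum(m[, ln] & m[, control]) / tot
    }, 0)
  } else NULL
  list(membership = m, totals = totals, private = private,
       trait_only = trait_only, all_lines = all_lines,
       shared_with_control = shared_ctrl)
}

#' Alternative allele frequency spectrum per line
#'
#' @param af a `line_af`.
#' @param n_bins number of equal-width bins partitioning [0, 1].
#' @return matrix (bins x lines) of site counts; bin labels on rownames.
#' @export
af_spectrum <- function(af, n_bins = 20) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  out <- sapply(colnames(af$p), function(ln) {
    p <- af$p[, ln]
    p <- p[!is.na(p)]
    tabulate(cut(p, breaks, include.lowest = TRUE), nbins = n_bins)
  })
  rownames(out) <- sprintf("(%0.3f,%0.3f]", breaks[-length(breaks)], breaks[-1])
  rownames(out)[1] <- sub("^\\(", "[", rownames(out)[1])
  out
}

#' Variant type counts and INDEL length distribution
#'
#' @param g a `genotype_data`.
#' @return list: `counts` (named vector SNP/INS/DEL), `indel_lengths`
#'   (table of |len(alt)-len(ref)| over INS/DEL sites) and
#'   `frac_indels_le_10bp`.
#' @export
variant_summary <- function(g) {
  counts <- c(SNP = sum(g$sites$vtype == "SNP"),
              INS = sum(g$sites$vtype == "INS"),
              DEL = sum(g$sites$vtype == "DEL"))
  len <- indel_length(g)[g$sites$vtype != "SNP"]
  list(counts = counts,
       indel_lengths = table(len),
       frac_indels_le_10bp = if (length(len)) mean(len <= 10) else NA_real_)
}

#' Windowed nucleotide diversity per line
#'
#' Per SNP site, pi is the mean pairwise difference among called chromosomes,
#' `2 j (n - j) / (n (n - 1))`; window pi sums the per-site values over the
#' SNPs in the window and divides by the window length in bp. Sites with
#' fewer than two called chromosomes are skipped. All tiled windows are
#' emitted with their SNP counts (no minimum), so downstream filtering
#' remains possible.
#'
#' @param g a `genotype_data` (only SNP sites are used).
#' @param lm a `line_map`.
#' @param w a [window_spec()].
#' @param include_pseudo include pseudo-lines.
#' @return data.frame: line, chrom, start, end, n_snps, pi.
#' @export
nucleotide_diversity_windows <- function(g, lm, w = window_spec(),
                                         include_pseudo = FALSE) {
  snp <- g$sites$vtype == "SNP"
  gs <- subset_sites(g, snp)
  af <- line_allele_frequencies(gs, lm, include_pseudo = include_pseudo)
  wins <- tile_windows(chrom_lengths_or_max(gs), w)
  site_gr <- GenomicRanges::GRanges(gs$sites$chrom,
                                    IRanges::IRanges(gs$sites$pos, width = 1))
  win_gr <- GenomicRanges::GRanges(wins$chrom,
                                   IRanges::IRanges(wins$start, wins$end))
  ov <- GenomicRanges::findOverlaps(site_gr, win_gr)
  out <- list()
  for (ln in colnames(af$p)) {
    jj <- af$j[, ln]; nn <- af$n[, ln]
    usable <- !is.na(nn) & nn >= 2
    pi_s <- ifelse(usable, 2 * jj * (nn - jj) / (nn * (nn - 1)), 0)
    contrib <- usable[S4Vectors::queryHits(ov)]
    pis <- tapply(pi_s[S4Vectors::queryHits(ov)][contrib],
                  S4Vectors::subjectHits(ov)[contrib], sum)
    cnt <- tapply(rep(1, sum(contrib)), S4Vectors::subjectHits(ov)[contrib], sum)
    res <- wins
    res$line <- ln
    res$n_snps <- 0L
    res$pi <- 0
    idx <- as.integer(names(pis))
    res$n_snps[idx] <- as.integer(cnt)
    res$pi[idx] <- pis / (res$end[idx] - res$start[idx] + 1)
    out[[ln]] <- res[, c("line", "chrom", "start", "end", "n_snps", "pi")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window_spec") <- w
  res
}

#' Identity-by-state distances and UPGMA clustering
#'
#' Pairwise allele-sharing distance `1 - shared / (2 m)` over the `m`
#' pairwise-complete sites of each sample pair (a pair of genotypes with
#' dosages a, b shares `2 - |a - b|` alleles), followed by average-linkage
#' (UPGMA) hierarchical clustering.
#'
#' @param g a `genotype_data`.
#' @param lm optional `line_map` (attached to the result for convenience).
#' @return list: `dist` (a `dist` object), `tree` (an `ape` phylo), `newick`
#'   (newick string).
#' @export
ibs_cluster <- function(g, lm = NULL) {
  ns <- length(g$samples)
  if (ns < 2) stop("at least two samples are required")
  d <- matrix(0, ns, ns, dimnames = list(g$samples, g$samples))
  for (i in seq_len(ns - 1)) {
    gi <- g$gt[, i]
    for (k in (i + 1):ns) {
      gk <- g$gt[, k]
      ok <- !is.na(gi) & !is.na(gk)
      m <- sum(ok)
      if (m == 0) stop("samples ", g$samples[i], " and ", g$samples[k],
                       " share no comparable sites")
      shared <- sum(2 - abs(gi[ok] - gk[ok]))
      d[i, k] <- d[k, i] <- 1 - shared / (2 * m)
    }
  }
  hd <- as.dist(d)
  tree <- ape::as.phylo(hclust(hd, method = "average"))
  list(dist = hd, tree = tree, newick = ape::write.tree(tree))
}
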