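#' Thin sites to a minimum pairwise distance
#'
#' Greedy left-to-right scan per chromosome: a site is kept when it lies at
#' least `min_dist` bp from the last kept site.
#'
#' @param sites data.frame with chrom, pos (sorted), or a `genotype_data`.
#' @param min_dist minimum distance in bp (default 100 kb).
#' @return integer vector of kept row indices (relative to the site table).
#' @export
thin_sites <- function(sites, min_dist = 100000) {
  if (inherits(sites, "genotype_data")) sites <- sites$sites
  keep <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (sites$pos[i] - last >= min_dist) {
        keep[i] <- TRUE
        last <- sites$pos[i]
      }
    }
  }
  which(keep)
}

#' Pairwise genotype correlation (r2) within a line
#'
#' Squared Pearson correlation of alt-allele dosage vectors over
#' pairwise-complete samples, for all same-chromosome site pairs no farther
#' apart than `max_dist`. Pairs with fewer than two complete samples or zero
#' dosage variance at either site are skipped. Sites should be thinned first
#' (see [thin_sites()]) so that pair distances respect the study's minimum.
#'
#' @param g a `genotype_data` (typically already subset to thinned sites).
#' @param lm a `line_map`.
#' @param line the (pseudo-)line to evaluate.
#' @param max_dist maximum pair distance in bp (default 5 Mb).
#' @return data.frame: chrom, pos_a, pos_b, dist, r2.
#' @export
ld_r2 <- function(g, lm, line, max_dist = 5e6) {
  cols <- match(line_samples(lm, line), g$samples)
  cols <- cols[!is.na(cols)]
  if (length(cols) < 2) stop("line ", line, " has fewer than 2 samples")
  gt <- g$gt[, cols, drop = FALSE]
  out <- list()
  for (ch in unique(g$sites$chrom)) {
    idx <- which(g$sites$chrom == ch)
    pos <- g$sites$pos[idx]
    for (ai in seq_along(idx)) {
      bs <- which(pos > pos[ai] & pos - pos[ai] <= max_dist)
      if (!length(bs)) next
      xa <- gt[idx[ai], ]
      for (bi in bs) {
        xb <- gt[idx[bi], ]
        ok <- !is.na(xa) & !is.na(xb)
        if (sum(ok) < 2) next
        va <- var(xa[ok]); vb <- var(xb[ok])
        if (is.na(va) || is.na(vb) || va == 0 || vb == 0) next
        r <- cor(xa[ok], xb[ok])
        out[[length(out) + 1L]] <- c(pos[ai], pos[bi], r^2)
        names(out)[length(out)] <- ch
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos_a = integer(),
                      pos_b = integer(), dist = integer(), r2 = numeric()))
  m <- do.call(rbind, out)
  data.frame(chrom = names(out), pos_a = m[, 1], pos_b = m[, 2],
             dist = m[, 2] - m[, 1], r2 = m[, 3], row.names = NULL)
}

#' Distance-binned LD decay curve
#'
#' Bins site pairs by distance (default 0.1-Mb bins from `min_dist` to
#' `max_dist`) and reports the arithmetic mean r2 and pair count per bin;
#' empty bins are reported with count 0.
#'
#' @param pairs output of [ld_r2()].
#' @param bin_width bin width in bp (default 0.1 Mb).
#' @param min_dist,max_dist distance range covered by the bins.
#' @return data.frame: bin_start, bin_end, bin_mid, n_pairs, mean_r2.
#' @export
decay_curve <- function(pairs, bin_width = 100000, min_dist = 100000,
                        max_dist = 5e6) {
  breaks <- seq(min_dist, max_dist, by = bin_width)
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_end = breaks[-1])
  out$bin_mid <- (out$bin_start + out$bin_end) / 2
  # bins [a, b) except the last, which is [a, b]
  bin <- as.integer(cut(pairs$dist, breaks, right = FALSE, include.lowest = TRUE))
  bin[pairs$dist == max_dist] <- nrow(out)
  ok <- !is.na(bin)
  out$n_pairs <- tabulate(bin[ok], nbins = nrow(out))
  sums <- tapply(pairs$r2[ok], bin[ok], sum)
  out$mean_r2 <- NA_real_
  idx <- as.integer(names(sums))
  out$mean_r2[idx] <- as.numeric(sums) / out$n_pairs[idx]
  out
}
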