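# Small fixture builders shared across test files.

# genotype_data from explicit matrices with sensible defaults
make_g <- function(gt, pos = NULL, chrom = "chr1", ref = "A", alt = "T",
                   dp = NULL, gq = NULL, pl = NULL, chrom_lengths = NULL) {
  gt <- as.matrix(gt)
  ns <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(ns) * 100L
  sites <- data.frame(chrom = rep_len(chrom, ns), pos = pos,
                      ref = rep_len(ref, ns), alt = rep_len(alt, ns),
                      stringsAsFactors = FALSE)
  samples <- colnames(gt)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(gt)))
  genotype_data(sites, samples, gt, dp = dp, gq = gq, pl = pl,
                chrom_lengths = chrom_lengths)
}

# random genotype_data fixture with missingness
rand_g <- function(seed, n_sites = 50, n_samples = 8, miss = 0.1,
                   chroms = "chr1") {
  set.seed(seed)
  gt <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
               n_sites, n_samples)
  gt[runif(length(gt)) < miss] <- NA
  chrom <- sample(chroms, n_sites, replace = TRUE)
  pos <- integer(n_sites)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(sample.int(1e6, k))
  }
  make_g(gt, pos = pos, chrom = chrom)
}

two_line_map <- function(n_a = 4, n_b = 4, prefix = c("A", "B")) {
  smp <- c(sprintf("s%02d", seq_len(n_a)), sprintf("s%02d", n_a + seq_len(n_b)))
  line_map(setNames(rep(prefix, c(n_a, n_b)), smp))
}

# tiny but complete breeding design for fast simulator tests
tiny_cfg <- function(seed, n_gen = 20, n_sites = 800, selected_b = TRUE,
                     ...) {
  sim_config(seed = seed,
             chrom_lengths = c(chr1 = 2e6, chr2 = 2e6), n_sites = n_sites,
             lines = data.frame(line = c("CTL", "SEL"),
                                n_pairs = c(25L, 12L),
                                selected = c(FALSE, selected_b),
                                prop_selected = c(1, 0.5),
                                bottleneck_gen = c(0L, as.integer(n_gen * 0.75)),
                                bottleneck_pairs = c(25L, 4L)),
             n_generations = n_gen, n_qtl = 10,
             n_sampled_high = 5, n_sampled_low = 5, ...)
}

# confident phred PL triples
PL_HOMREF <- c(0, 90, 180)
PL_HET <- c(90, 0, 90)
PL_HOMALT <- c(180, 90, 0)

# genotype_data with PL/DP/GQ built from a dosage matrix assuming confident
# calls (for RoH tests)
make_g_pl <- function(gt, pos, chrom = "chr1", chrom_lengths = NULL) {
  gt <- as.matrix(gt)
  pick <- function(k) rbind(PL_HOMREF, PL_HET, PL_HOMALT)[gt + 1L, k]
  pl <- list(RR = matrix(pick(1), nrow(gt)),
             RA = matrix(pick(2), nrow(gt)),
             AA = matrix(pick(3), nrow(gt)))
  make_g(gt, pos = pos, chrom = chrom,
         dp = matrix(30L, nrow(gt), ncol(gt)),
         gq = matrix(90L, nrow(gt), ncol(gt)),
         pl = pl, chrom_lengths = chrom_lengths)
}

# SV record row builder with well-supported defaults
sv_rec <- function(sample = "s01", line = "A", coverage_set = "high",
                   caller = "manta", svtype = "DEL", chrom = "chr1",
                   start = 10000, end = 20000, gt = "het", gq = 60,
                   mapq = 60, su = 10, depth = 20, depth_ratio = 1,
                   cross_chrom_fraction = 0) {
  data.frame(sample = sample, line = line, coverage_set = coverage_set,
             caller = caller, svtype = svtype, chrom = chrom, start = start,
             end = end, length = end - start, gt = gt, gq = gq, mapq = mapq,
             su = su, depth = depth, depth_ratio = depth_ratio,
             cross_chrom_fraction = cross_chrom_fraction,
             stringsAsFactors = FALSE)
}

# compare values ignoring names/attributes picked up from dimnames
eqn <- function(object, expected, ...) {
  testthat::expect_equal(unname(object), unname(expected), ...)
}
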