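test_that("per-line allele frequencies match exhaustive counting", {
  lm <- two_line_map(3, 3)
  gt <- rbind(c(0L, 1L, 2L, 0L, 0L, 0L),
              c(NA, NA, NA, 1L, 1L, 1L),
              c(2L, 2L, 2L, NA, 0L, 1L))
  g <- make_g(gt)
  af <- line_allele_frequencies(g, lm)
  eqn(af$j[1, "A"], 3); eqn(af$n[1, "A"], 6)
  eqn(af$p[1, "A"], 0.5)
  expect_true(is.na(af$p[2, "A"]))          # all missing in line A
  eqn(af$p[2, "B"], 0.5)
  eqn(af$het[3, "B"], 0.5)

  g2 <- rand_g(61, n_sites = 50, n_samples = 6, miss = 0.2)
  af2 <- line_allele_frequencies(g2, lm)
  for (i in seq_len(50)) for (ln in c("A", "B")) {
    cols <- which(lm$assignment[g2$samples] == ln)
    x <- g2$gt[i, cols]
    eqn(af2$j[i, ln], sum(x, na.rm = TRUE))
    eqn(af2$n[i, ln], 2 * sum(!is.na(x)))
  }
})

test_that("pseudo-lines pool their member samples", {
  lm <- line_map(setNames(c("A", "A", "B", "B"), sprintf("s%02d", 1:4)),
                 pseudo_lines = list(AB = c("A", "B")))
  g <- make_g(rbind(c(0L, 1L, 2L, NA)))
  af <- line_allele_frequencies(g, lm)
  eqn(af$j[1, "AB"], 3)
  eqn(af$n[1, "AB"], 6)
})

test_that("site classification is a partition with correct boundaries", {
  lm <- two_line_map(3, 3)
  gt <- rbind(c(2L, 2L, 2L, 0L, 0L, 0L),   # A fixed_alt, B fixed_ref
              c(0L, 0L, 1L, 1L, 1L, 1L),   # both polymorphic
              c(NA, NA, NA, 2L, 2L, 2L))   # A uncalled, B fixed_alt
  cls <- classify_sites(line_allele_frequencies(make_g(gt), lm))
  eqn(cls[, "A"], c("fixed_alt", "polymorphic", "uncalled"))
  eqn(cls[, "B"], c("fixed_ref", "polymorphic", "fixed_alt"))

  # a single alt allele among many chromosomes is still polymorphic
  gt1 <- matrix(0L, 1, 6); gt1[1, 1] <- 1L
  cls1 <- classify_sites(line_allele_frequencies(make_g(gt1), lm))
  eqn(cls1[1, "A"], "polymorphic")

  g2 <- rand_g(71, n_sites = 100, n_samples = 6, miss = 0.3)
  af2 <- line_allele_frequencies(g2, lm)
  cls2 <- classify_sites(af2)
  for (ln in c("A", "B")) {
    p <- af2$p[, ln]
    expect_equal(unname(cls2[, ln]),
                 ifelse(is.na(p), "uncalled",
                        ifelse(p == 0, "fixed_ref",
                               ifelse(p == 1, "fixed_alt", "polymorphic"))))
  }
})

test_that("shared/private set counts equal power-set enumeration", {
  lm3 <- line_map(setNames(rep(c("A", "B", "C"), each = 2),
                           sprintf("s%02d", 1:6)))
  gt <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L),   # private to A
              c(1L, 0L, 2L, 1L, 1L, 0L),   # in all three
              c(0L, 0L, 1L, 0L, 0L, 0L))   # private to B
  sets <- shared_private_sets(line_allele_frequencies(make_g(gt), lm3),
                              lines = c("A", "B", "C"), control = character(0))
  expect_equal(unname(sets$private), c(1, 1, 0))
  expect_equal(sets$all_lines, 1)

  set.seed(81)
  g2 <- rand_g(81, n_sites = 200, n_samples = 6, miss = 0.2)
  af2 <- line_allele_frequencies(g2, lm3)
  sets2 <- shared_private_sets(af2, lines = c("A", "B", "C"), control = "C")
  # enumeration oracle over the 2^3 membership patterns
  memb <- sapply(c("A", "B", "C"), function(ln) {
    cols <- which(lm3$assignment[g2$samples] == ln)
    apply(g2$gt[, cols, drop = FALSE], 1,
          function(x) sum(x, na.rm = TRUE) >= 1)
  })
  expect_equal(unname(sets2$totals), unname(colSums(memb)))
  expect_equal(unname(sets2$private), unname(sapply(1:3, function(k)
    sum(memb[, k] & rowSums(memb) == 1))))
  expect_equal(sets2$all_lines, sum(rowSums(memb) == 3))
  expect_equal(sets2$trait_only, sum(memb[, "A"] & memb[, "B"] & !memb[, "C"]))
  expect_equal(unname(sets2$shared_with_control["A"]),
               sum(memb[, "A"] & memb[, "C"]) / sum(memb[, "A"]))
})

test_that("allele frequency spectra bin correctly", {
  lm <- two_line_map(2, 2)
  # line A frequencies 0, .25, .5, .75, 1 by construction
  gt <- cbind(c(0L, 0L, 1L, 1L, 2L), c(0L, 1L, 1L, 2L, 2L),
              matrix(0L, 5, 2))
  af <- line_allele_frequencies(make_g(gt), lm)
  sp <- af_spectrum(af, n_bins = 4)
  expect_equal(sum(sp[, "A"]), 5)
  expect_equal(unname(sp[, "A"]), c(2, 1, 1, 1))
  expect_error(af_spectrum(af, n_bins = 0))

  g2 <- rand_g(91, n_sites = 120, n_samples = 4, miss = 0.15)
  af2 <- line_allele_frequencies(g2, lm)
  sp2 <- af_spectrum(af2, n_bins = 10)
  p <- af2$p[, "B"]; p <- p[!is.na(p)]
  oracle <- table(cut(p, seq(0, 1, 0.1), include.lowest = TRUE))
  expect_equal(unname(sp2[, "B"]), unname(as.integer(oracle)))
})

test_that("variant summary counts types and INDEL lengths", {
  sites <- data.frame(chrom = "chr1", pos = c(1L, 10L, 20L, 30L),
                      ref = c("A", "A", "A", "AT"),
                      alt = c("ATT", "ATTTTT", "ATTTTTTTTTTTT", "A"))
  g <- genotype_data(sites, "s1", matrix(1L, 4, 1))
  vs <- variant_summary(g)
  expect_equal(unname(vs$counts), c(0, 3, 1))
  expect_equal(vs$frac_indels_le_10bp, 0.75)
  g0 <- make_g(matrix(0L, 2, 1))
  expect_equal(unname(variant_summary(g0)$counts), c(2, 0, 0))
})

test_that("windowed nucleotide diversity matches the pairwise definition", {
  lm <- two_line_map(2, 2)
  # one SNP in the first window: line A has n = 4 chromosomes, j = 2
  gt <- rbind(c(1L, 1L, 0L, 0L))
  g <- make_g(gt, pos = 1000L, chrom_lengths = c(chr1 = 100000))
  pw <- nucleotide_diversity_windows(g, lm, window_spec(50000, 25000))
  w1 <- pw[pw$line == "A" & pw$start == 1, ]
  expect_equal(w1$pi, 2 * 2 * 2 / (4 * 3) / 50000)
  expect_equal(w1$n_snps, 1)
  # windows containing no variant site have pi = 0
  expect_equal(pw$pi[pw$line == "A" & pw$start == 50001], 0)
  # a fully fixed line has pi = 0 everywhere
  gt2 <- rbind(c(2L, 2L, 0L, 1L), c(0L, 0L, 1L, 1L))
  g2 <- make_g(gt2, pos = c(1000L, 2000L), chrom_lengths = c(chr1 = 50000))
  pw2 <- nucleotide_diversity_windows(g2, lm, window_spec(50000, 25000))
  expect_true(all(pw2$pi[pw2$line == "A"] == 0))
  # invariance under ref/alt relabeling (dosage flip 2 - d)
  g3 <- rand_g(101, n_sites = 40, n_samples = 4, miss = 0.1)
  g4 <- g3; g4$gt <- 2L - g3$gt
  p3 <- nucleotide_diversity_windows(g3, lm, window_spec(10000, 5000))
  p4 <- nucleotide_diversity_windows(g4, lm, window_spec(10000, 5000))
  expect_equal(p3$pi, p4$pi)
  # bound: at most 1 per usable site (n = 2 chromosomes), over the window
  expect_true(all(p3$pi <= pmax(p3$n_snps, 1) / (p3$end - p3$start + 1) + 1e-12))
})

test_that("IBS distances and UPGMA clustering behave correctly", {
  # duplicate samples sit at distance zero
  gt <- cbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 0L))
  colnames(gt) <- c("dup1", "dup2", "far")
  g <- make_g(gt)
  ib <- ibs_cluster(g)
  dm <- as.matrix(ib$dist)
  expect_equal(dm["dup1", "dup2"], 0)
  # hand count: dup1 vs far shares (0,2)->0 (1,1)->2 (2,0)->0 (1,0)->1 of 8
  expect_equal(dm["dup1", "far"], 1 - 3 / 8)
  expect_s3_class(ib$tree, "phylo")
  expect_match(ib$newick, "dup1")

  # samples cluster by line on simulated data
  sim <- simulate_dataset(tiny_cfg(123), emulate = FALSE)
  ib2 <- ibs_cluster(sim$g, sim$lm)
  for (ln in c("CTL", "SEL")) {
    tips <- line_samples(sim$lm, ln)
    expect_true(ape::is.monophyletic(ib2$tree, tips))
  }
})
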