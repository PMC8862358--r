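test_that("Weir-Cockerham components reproduce hand-derived values", {
  # fixed difference between populations forces fst = 1
  r1 <- wc_fst_site(10, 5, 0, 0, 5, 0)
  expect_equal(r1$a, 0.5); expect_equal(r1$b, 0); expect_equal(r1$c, 0)
  expect_equal(r1$fst, 1)
  # jointly monomorphic: undefined
  r2 <- wc_fst_site(10, 5, 0, 10, 5, 0)
  expect_true(is.na(r2$fst))
  # hand-evaluated mixed case
  r3 <- wc_fst_site(8, 5, 0.4, 2, 5, 0.4)
  expect_equal(r3$a, 0.165, tolerance = 1e-12)
  expect_equal(r3$b, -0.025, tolerance = 1e-12)
  expect_equal(r3$c, 0.2, tolerance = 1e-12)
  expect_equal(r3$fst, 0.165 / 0.34, tolerance = 1e-12)
})

test_that("vectorized estimator matches the brute-force oracle and is symmetric", {
  set.seed(111)
  for (rep in 1:200) {
    cc <- random_wc_config()
    got <- wc_fst_site(cc$j1, cc$n1, cc$h1, cc$j2, cc$n2, cc$h2)
    want <- wc_oracle(c(cc$j1, cc$j2), c(cc$n1, cc$n2), c(cc$h1, cc$h2))
    expect_equal(got$a, want$a, tolerance = 1e-12)
    expect_equal(got$b, want$b, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    expect_equal(got$fst, want$fst, tolerance = 1e-12)
    # symmetry in population order
    swap <- wc_fst_site(cc$j2, cc$n2, cc$h2, cc$j1, cc$n1, cc$h1)
    expect_equal(swap$fst, got$fst, tolerance = 1e-12)
    # invariance under ref/alt relabeling
    flip <- wc_fst_site(2 * cc$n1 - cc$j1, cc$n1, cc$h1,
                        2 * cc$n2 - cc$j2, cc$n2, cc$h2)
    expect_equal(flip$fst, got$fst, tolerance = 1e-12)
  }
})

test_that("window means use defined sites only and honor min_snps", {
  set.seed(121)
  fsts <- c(1, 0, -0.1, 0.2, 0.4, 0.3, 0.5, 0.6, 0.35, 0.25)
  sf <- data.frame(chrom = "chr1", pos = seq(1000, 46000, by = 5000),
                   a = 1, b = 1, c = 1, fst = fsts)
  w <- windowed_fst(sf, window_spec(50000, 50000, min_snps = 10),
                    chrom_lengths = c(chr1 = 50000))
  expect_equal(nrow(w), 1)
  expect_equal(w$mean_fst, mean(fsts))
  # 9 defined sites < min 10: window omitted
  sf$fst[3] <- NA
  w2 <- windowed_fst(sf, window_spec(50000, 50000, min_snps = 10),
                     chrom_lengths = c(chr1 = 50000))
  expect_equal(nrow(w2), 0)

  # random placement vs brute-force window assignment
  pos <- sort(sample.int(2e5, 150))
  sf3 <- data.frame(chrom = "chr1", pos = pos, a = 1, b = 1, c = 1,
                    fst = runif(150, -0.1, 1))
  ws <- window_spec(50000, 25000, min_snps = 1)
  w3 <- windowed_fst(sf3, ws, chrom_lengths = c(chr1 = 2e5))
  starts <- seq(1, 2e5, by = 25000)
  for (s in starts) {
    inw <- sf3$fst[pos >= s & pos <= s + 49999]
    row <- w3[w3$start == s, ]
    if (length(inw) >= 1) {
      expect_equal(row$mean_fst, mean(inw))
      expect_equal(row$n_snps, length(inw))
    } else {
      expect_equal(nrow(row), 0)
    }
  }
})

test_that("z-standardization treats the X chromosome separately", {
  w <- data.frame(chrom = c("chr1", "chr1", "chr1"), start = 1, end = 2,
                  n_snps = 10, mean_fst = c(1, 2, 3))
  z <- zscore_windows(w)
  expect_equal(z$z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)

  # identical X and autosomal distributions give identical z values
  w2 <- data.frame(chrom = rep(c("chr1", "X"), each = 5), start = 1:10,
                   end = 2, n_snps = 10, mean_fst = rep(c(.1, .2, .3, .4, .5), 2))
  z2 <- zscore_windows(w2)
  expect_equal(z2$z[1:5], z2$z[6:10])

  # each group standardizes to mean 0 sd 1 (population divisor)
  set.seed(131)
  w3 <- data.frame(chrom = sample(c("chr1", "chr2", "X"), 60, replace = TRUE),
                   start = 1:60, end = 2, n_snps = 10, mean_fst = runif(60))
  z3 <- zscore_windows(w3)
  for (grp in list(z3$z[z3$chrom != "X"], z3$z[z3$chrom == "X"])) {
    expect_equal(mean(grp), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(grp^2)), 1, tolerance = 1e-9)
  }
  # oracle: direct two-group standardization
  a <- w3$mean_fst[w3$chrom != "X"]
  expect_equal(z3$z[w3$chrom != "X"],
               (a - mean(a)) / sqrt(mean((a - mean(a))^2)), tolerance = 1e-12)
})

test_that("genome-wide mean FST is ~0 for identical lines and matches hand fixture", {
  lm <- two_line_map(12, 12)
  set.seed(141)
  half <- matrix(sample(0:2, 60 * 12, replace = TRUE), 60, 12)
  g <- make_g(cbind(half, half), pos = seq_len(60) * 500L,
              chrom_lengths = c(chr1 = 30000))
  m <- genomewide_mean_fst(g, lm, w = window_spec(30000, 30000, min_snps = 1))
  # small negative values are the estimator's finite-sample behavior
  expect_lt(m["A", "B"], 0.02)
  expect_gt(m["A", "B"], -0.07)
  expect_true(is.na(m["A", "A"]))
  m2 <- genomewide_mean_fst(g, lm, method = "ratio_of_sums")
  expect_lt(abs(m2["A", "B"]), 0.08)

  # hand-built two-window fixture: mean of window means
  sf <- data.frame(chrom = "chr1", pos = c(10, 20, 60010, 60020),
                   a = 1, b = 1, c = 1, fst = c(0.2, 0.4, 0.6, 0.8))
  wf <- windowed_fst(sf, window_spec(50000, 50000, min_snps = 2),
                     chrom_lengths = c(chr1 = 100000))
  expect_equal(mean(wf$mean_fst), mean(c(0.3, 0.7)))
})

toy_contrasts <- function(n = 20, seed = 151) {
  set.seed(seed)
  base <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 25000 + 1,
                     end = (0:(n - 1)) * 25000 + 50000, n_snps = 20)
  tgt <- base; tgt$mean_fst <- runif(n, 0.2, 0.5); tgt$mean_fst[7] <- 0.99
  o1 <- base; o1$mean_fst <- runif(n, 0.2, 0.5); o1$mean_fst[7] <- 0.01
  o2 <- base; o2$mean_fst <- runif(n, 0.2, 0.5); o2$mean_fst[7] <- 0.02
  list(T = tgt, O1 = o1, O2 = o2)
}

test_that("RDD detection flags the unique extreme window and merges regions", {
  ct <- toy_contrasts()
  rdd <- detect_rdd(ct, "T")
  expect_equal(nrow(rdd$regions), 1)
  expect_true(rdd$regions$start <= ct$T$start[7] &&
                rdd$regions$end >= ct$T$end[7])
  expect_equal(nrow(rdd$windows), 1)

  # identical distributions across contrasts: nothing can be top and bottom
  same <- ct$T
  rdd2 <- detect_rdd(list(A = same, B = same, C = same), "A")
  expect_equal(nrow(rdd2$regions), 0)

  # windows missing from another contrast are disqualified
  ct3 <- ct
  ct3$O1 <- ct3$O1[-7, ]
  rdd3 <- detect_rdd(ct3, "T")
  expect_equal(nrow(rdd3$regions), 0)
})

test_that("RDD output is monotone in its thresholds", {
  set.seed(161)
  n <- 60
  base <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 25000 + 1,
                     end = (0:(n - 1)) * 25000 + 50000, n_snps = 15)
  mk <- function() { d <- base; d$mean_fst <- runif(n); d }
  ct <- list(T = mk(), O1 = mk(), O2 = mk())
  key <- function(w) paste(w$chrom, w$start)
  for (rep in 1:5) {
    ct$T$mean_fst <- runif(n); ct$O1$mean_fst <- runif(n)
    loose <- detect_rdd(ct, "T", top_pct = 80, bottom_pct = 30)
    strict <- detect_rdd(ct, "T", top_pct = 95, bottom_pct = 10)
    expect_true(all(key(strict$windows) %in% key(loose$windows)))
  }
})

test_that("pseudo-line contrasts sharing samples with the target are excluded", {
  ct <- toy_contrasts()
  names(ct) <- c("DUK", "DUC", "FERT")
  lm <- line_map(setNames(c("DUK", "DUC", "FZTDU"), c("a", "b", "c")),
                 pseudo_lines = list(FERT = c("DUK", "DUC")))
  rdd <- detect_rdd(ct, "DUK", lm = lm)
  expect_equal(rdd$thresholds$others_used, "DUC")
  # for target FERT both member-line contrasts drop out; with no independent
  # contrast left this is an error, not a silent scan
  expect_error(detect_rdd(ct, "FERT", lm = lm), "no other contrasts")
})

test_that("gene annotation uses any-overlap, strand-agnostic", {
  genes <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                                  IRanges::IRanges(c(100, 900, 100),
                                                   c(200, 1100, 200)),
                                  strand = c("+", "-", "+"))
  genes$gene_id <- c("g1", "g2", "g3")
  regions <- data.frame(chrom = "chr1", start = 150, end = 900)
  ann <- annotate_regions(regions, genes)
  # g1 inside, g2 overlaps by exactly 1 bp at the edge, g3 wrong chromosome
  expect_equal(ann$genes, "g1,g2")
  expect_equal(ann$n_genes, 2L)

  set.seed(171)
  gs <- sort(sample.int(1e5, 30))
  genes2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gs, gs + 500))
  genes2$gene_id <- sprintf("g%02d", 1:30)
  rs <- sort(sample.int(1e5, 10))
  regions2 <- data.frame(chrom = "chr1", start = rs, end = rs + 2000)
  ann2 <- annotate_regions(regions2, genes2)
  for (i in 1:10) {
    hit <- which(gs <= regions2$end[i] & gs + 500 >= regions2$start[i])
    expect_equal(ann2$n_genes[i], length(hit))
  }
})
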