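test_that("VCF round-trip preserves GT/DP/GQ/PL and is byte-stable", {
  set.seed(11)
  gt_true <- matrix(sample(0:2, 10 * 6, replace = TRUE), 10, 6)
  sites <- data.frame(chrom = rep(c("chr1", "chr2"), each = 5),
                      pos = rep(c(100L, 250L, 900L, 1500L, 4000L), 2),
                      ref = "A", alt = "T")
  g <- sequence_emulator(gt_true, sites, sprintf("s%02d", 1:6),
                         depth_mean = 20,
                         chrom_lengths = c(chr1 = 5000, chr2 = 5000))
  expect_equal(nrow(g$sites), 10)
  expect_equal(length(g$samples), 6)

  f1 <- tempfile(fileext = ".vcf")
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(g, f1)
  g2 <- read_vcf(f1)
  expect_equal(g2$gt, g$gt, ignore_attr = TRUE)
  expect_equal(unname(g2$dp), unname(g$dp))
  expect_equal(unname(g2$gq), unname(g$gq))
  for (k in c("RR", "RA", "AA"))
    expect_equal(unname(g2$pl[[k]]), unname(g$pl[[k]]))
  expect_equal(g2$sites[, c("chrom", "pos", "ref", "alt")],
               g$sites[, c("chrom", "pos", "ref", "alt")])
  write_vcf(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("multi-allelic records are skipped and counted", {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", "s2"), collapse = "\t"))
  recs <- sapply(1:10, function(i)
    paste(c("chr1", i * 100, ".", "A", if (i == 4) "T,G" else "T", ".",
            "PASS", ".", "GT", "0/1", "1/1"), collapse = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(c(lines, recs), f)
  g <- read_vcf(f)
  expect_equal(nrow(g$sites), 9)
  expect_false(400 %in% g$sites$pos)
  expect_equal(g$log[[1]]$n_multiallelic_skipped, 1)
})

test_that("genotype filters mask boundary DP/GQ cells and are idempotent", {
  # sample 1: constant depth 20 so mean = 20, sd = 0
  gt <- matrix(1L, 6, 2)
  dp <- cbind(c(3L, 20L, 20L, 20L, 20L, 20L), rep(10L, 6))
  gq <- cbind(c(99L, 20L, 19L, 99L, 99L, 99L), rep(99L, 6))
  g <- make_g(gt, dp = dp, gq = gq)
  gf <- apply_genotype_filters(g)
  expect_true(is.na(gf$gt[1, 1]))   # DP = 3 < 4 despite GQ 99
  expect_equal(unname(gf$gt[2, 1]), 1L)     # DP and GQ exactly at threshold: retained
  expect_true(is.na(gf$gt[3, 1]))   # GQ = 19 < 20 is strict
  expect_equal(unname(gf$gt[4, 1]), 1L)
  gff <- apply_genotype_filters(gf)
  expect_identical(gff$gt, gf$gt)   # idempotent
  # dosages of surviving cells are unchanged
  expect_identical(gf$gt[!is.na(gf$gt)], g$gt[!is.na(gf$gt)])
})

test_that("per-sample high-depth outliers are masked against mean + 3 sd", {
  set.seed(21)
  n <- 101
  dp <- matrix(10L, n, 1)
  dp[n, 1] <- 1000L
  gt <- matrix(1L, n, 1)
  gq <- matrix(99L, n, 1)
  g <- make_g(gt, dp = dp, gq = gq)
  # direct arithmetic oracle (population sd over all recorded depths)
  mu <- mean(dp); sdv <- sqrt(mean((dp - mu)^2))
  expect_gt(1000, mu + 3 * sdv)
  expect_lt(10, mu + 3 * sdv)
  gf <- apply_genotype_filters(g)
  expect_equal(nrow(gf$sites), n - 1)       # all-missing outlier site dropped
  expect_true(all(!is.na(gf$gt)))
  expect_false(1000 %in% gf$dp)
})

test_that("site support filter matches a brute-force per-line count oracle", {
  set.seed(31)
  lm <- two_line_map(4, 2)
  g <- rand_g(31, n_sites = 20, n_samples = 6, miss = 0.35)
  thr <- c(A = 2, B = 1)
  keep_oracle <- sapply(seq_len(20), function(i) {
    all(vapply(c("A", "B"), function(ln) {
      cols <- which(lm$assignment[g$samples] == ln)
      sum(!is.na(g$gt[i, cols])) >= thr[[ln]]
    }, TRUE))
  })
  gf <- site_support_filter(g, lm, min_support = 2, overrides = c(B = 1))
  expect_equal(gf$sites$pos, g$sites$pos[keep_oracle])

  # one short of the threshold drops the site
  gt <- matrix(1L, 1, 6); gt[1, 4] <- NA
  g1 <- make_g(gt)
  expect_equal(nrow(site_support_filter(g1, lm, min_support = 4,
                                        overrides = c(B = 2))$sites), 0)
  expect_equal(nrow(site_support_filter(g1, lm, min_support = 3,
                                        overrides = c(B = 2))$sites), 1)
})

test_that("interval exclusion removes only INDELs overlapping the track", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 100L, 300L),
                      ref = c("ATTTTT", "A", "A"), alt = c("A", "T", "ATT"))
  g <- genotype_data(sites, "s1", matrix(1L, 3, 1))
  track <- interval_track("chr1", 95, 102)
  gf <- exclude_intervals(g, track)
  # DEL footprint [100,105) overlaps; SNP at same pos untouched
  expect_equal(gf$sites$vtype, c("SNP", "INS"))

  set.seed(41)
  pos <- sort(sample.int(1e5, 50))
  len <- sample(1:20, 50, replace = TRUE)
  ref <- vapply(len, function(l) paste(rep("A", l + 1), collapse = ""), "")
  sites <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = "A")
  gg <- genotype_data(sites, "s1", matrix(1L, 50, 1))
  st <- sort(sample.int(1e5, 10)); en <- st + sample(50:500, 10)
  trk <- interval_track("chr1", st, en)
  # oracle works on the sorted site order used inside genotype_data
  o <- order(sites$pos)
  rm_oracle <- overlap_oracle(pos[o], len[o], st, en)
  gf2 <- exclude_intervals(gg, trk)
  expect_equal(gf2$sites$pos, sort(pos)[!rm_oracle])
})

test_that("filter chain never increases site counts and logs each step", {
  set.seed(51)
  lm <- two_line_map(4, 4)
  gt_true <- matrix(sample(0:2, 60 * 8, replace = TRUE), 60, 8)
  g <- sequence_emulator(gt_true, data.frame(chrom = "chr1",
                                             pos = seq_len(60) * 50L),
                         names(lm$assignment), depth_mean = 8)
  n0 <- nrow(g$sites)
  g1 <- apply_genotype_filters(g)
  g2 <- site_support_filter(g1, lm, min_support = 3)
  expect_lte(nrow(g1$sites), n0)
  expect_lte(nrow(g2$sites), nrow(g1$sites))
  steps <- vapply(g2$log, function(x) x$step, "")
  expect_true(all(c("apply_genotype_filters", "site_support_filter") %in% steps))
  rep_file <- tempfile(fileext = ".json")
  write_filter_report(g2, rep_file)
  expect_true(jsonlite::validate(paste(readLines(rep_file), collapse = "")))
})
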