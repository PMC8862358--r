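test_that("caller-specific filters apply exact boundary rules", {
  recs <- rbind(
    sv_rec(caller = "manta", mapq = 29),                  # drop
    sv_rec(caller = "manta", mapq = 30),                  # keep
    sv_rec(caller = "manta", depth_ratio = 3.5),          # drop
    sv_rec(caller = "manta", gq = 19),                    # drop
    sv_rec(caller = "manta", depth = 4),                  # drop
    sv_rec(caller = "whamg", start = 1000, end = 1049),   # drop (49 bp)
    sv_rec(caller = "whamg", start = 1000, end = 1050),   # keep (50 bp)
    sv_rec(caller = "whamg", start = 1000, end = 2.1e6),  # drop (> 2 Mb)
    sv_rec(caller = "whamg", cross_chrom_fraction = 0.5), # drop
    sv_rec(caller = "lumpy", su = 4),                     # drop
    sv_rec(caller = "lumpy", su = 5),                     # keep
    sv_rec(caller = "lumpy", gq = 19))                    # drop
  out <- filter_caller_records(recs)
  expect_equal(nrow(out), 3)
  expect_equal(sort(attr(out, "drop_counts")[["manta_mapq"]]), 1)

  set.seed(221)
  rand <- do.call(rbind, lapply(1:120, function(i)
    sv_rec(caller = sample(c("manta", "whamg", "lumpy"), 1),
           start = 1000, end = 1000 + sample(10:3e6, 1),
           mapq = sample(20:60, 1), gq = sample(10:60, 1),
           su = sample(2:12, 1), depth = sample(2:30, 1),
           depth_ratio = runif(1, 0.5, 4),
           cross_chrom_fraction = runif(1, 0, 0.3))))
  out2 <- filter_caller_records(rand)
  expect_equal(nrow(out2), sum(sv_filter_oracle(rand)))
  expect_equal(out2$start, rand$start[sv_filter_oracle(rand)])
  expect_error(filter_caller_records(sv_rec(caller = "delly")), "unknown caller")
})

test_that("consensus merging needs two callers and respects type/tolerance", {
  recs <- rbind(
    sv_rec(caller = "manta", sample = "s01", start = 10000, end = 20000),
    sv_rec(caller = "lumpy", sample = "s02", start = 10200, end = 20150),
    sv_rec(caller = "manta", svtype = "DUP", sample = "s03",
           start = 10000, end = 20000),
    sv_rec(caller = "whamg", svtype = "DUP", sample = "s04",
           start = 10000, end = 20000),
    sv_rec(caller = "manta", sample = "s05", start = 500000, end = 600000))
  cons <- consensus_merge(recs, breakpoint_tol = 1000, min_callers = 2)
  expect_equal(nrow(cons), 2)   # DEL pair and DUP pair; singleton dropped
  del <- cons[cons$svtype == "DEL", ]
  expect_equal(del$n_callers, 2)
  expect_equal(del$start, 10100)  # median of member breakpoints
  expect_equal(del$samples, "s01,s02")
  # DEL and DUP at identical coordinates never merge
  expect_equal(nrow(cons[cons$svtype == "DUP", ]), 1)
  # insertions are parsed but excluded by default
  ins <- rbind(sv_rec(caller = "manta", svtype = "INS"),
               sv_rec(caller = "lumpy", svtype = "INS"))
  expect_equal(nrow(consensus_merge(ins)), 0)
})

test_that("clustering equals connected components and ignores input order", {
  set.seed(231)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    st <- sample.int(50000, 1)
    sv_rec(caller = sample(c("manta", "whamg", "lumpy"), 1),
           sample = sprintf("s%02d", sample(12, 1)),
           svtype = sample(c("DEL", "DUP"), 1),
           start = st, end = st + sample(500:5000, 1))
  }))
  tol <- 800
  cons <- consensus_merge(recs, breakpoint_tol = tol, min_callers = 1)
  # oracle: per svtype, BFS components; count clusters
  n_oracle <- 0L
  for (tp in unique(recs$svtype)) {
    rr <- recs[recs$svtype == tp, ]
    n_oracle <- n_oracle + length(unique(sv_cluster_oracle(rr, tol)))
  }
  expect_equal(nrow(cons), n_oracle)
  perm <- sample(nrow(recs))
  cons2 <- consensus_merge(recs[perm, ], breakpoint_tol = tol, min_callers = 1)
  o1 <- cons[order(cons$svtype, cons$start), ]
  o2 <- cons2[order(cons2$svtype, cons2$start), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("sample support, coverage union and classification work end to end", {
  mk_cons <- function(n_samples, line = "A", cov = "high", start = 10000,
                      svtype = "DEL", hom = TRUE) {
    smp <- paste(sprintf("%s_s%02d", line, seq_len(n_samples)), collapse = ",")
    data.frame(line = line, coverage_set = cov, svtype = svtype,
               chrom = "chr1", start = start, end = start + 5000,
               n_callers = 2, callers = "manta,lumpy", n_samples = n_samples,
               samples = smp, hom_samples = if (hom) smp else "",
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(sample_support_filter(mk_cons(10))), 1)
  expect_equal(nrow(sample_support_filter(mk_cons(9))), 0)

  high <- rbind(mk_cons(10, start = 10000), mk_cons(10, start = 90000))
  low <- rbind(mk_cons(10, cov = "low", start = 10300),
               mk_cons(10, cov = "low", start = 500000))
  un <- union_coverage_sets(high, low)
  expect_equal(nrow(un), 3)
  expect_equal(sort(un$coverage_sets), c("high", "high,low", "low"))

  # identical sets collapse to one copy each
  un2 <- union_coverage_sets(mk_cons(10), mk_cons(10, cov = "low"))
  expect_equal(nrow(un2), 1)

  lm <- line_map(setNames(rep(c("A", "B"), each = 10),
                          c(sprintf("A_s%02d", 1:10), sprintf("B_s%02d", 1:10))))
  sets <- rbind(mk_cons(10, "A", start = 10000),
                mk_cons(10, "B", start = 10200),      # matches A's -> shared
                mk_cons(10, "A", start = 300000),     # line specific, fixed
                mk_cons(5, "A", start = 600000, hom = FALSE),  # not fixed
                mk_cons(10, "A", start = 900000))     # masked out
  sets$coverage_sets <- "high"
  masks <- list(interval_track("chr1", 898000, 910000, name = "gap"))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301000, 302000))
  genes$gene_id <- "geneX"
  cl <- classify_and_mask(sets, masks = masks, genes = genes, lm = lm)
  expect_equal(nrow(cl), 4)                       # gap-overlapping SV removed
  expect_false(cl$line_specific[cl$start == 10000])
  expect_true(cl$line_specific[cl$start == 300000])
  expect_true(cl$fixed[cl$start == 300000])
  expect_false(cl$fixed[cl$start == 600000])      # het carriers, not all samples
  expect_true(cl$genic[cl$start == 300000])
  summ <- sv_summary_table(cl)
  arow <- summ[summ$line == "A", ]
  expect_equal(arow$total_DEL, 3)
  expect_equal(arow$ls_genic_DEL, 1)
})

test_that("planted line-private fixed deletions are recovered end to end", {
  set.seed(241)
  samples <- c(sprintf("DUK_%02d", 1:12), sprintf("FZTDU_%02d", 1:12))
  lm <- line_map(setNames(rep(c("DUK", "FZTDU"), each = 12), samples))
  coverage <- setNames(rep(rep(c("high", "low"), each = 6), 2), samples)
  planted <- data.frame(chrom = "chr1",
                        start = c(1e6, 5e6, 9e6),
                        end = c(1.02e6, 5.05e6, 9.01e6),
                        svtype = "DEL",
                        lines = c("DUK", "DUK", "all"),
                        fixed = c(TRUE, TRUE, TRUE))
  recs <- simulate_sv_records(planted, lm, coverage, n_background = 40,
                              chrom_lengths = c(chr1 = 5e7))
  res <- sv_pipeline(recs, lm, min_samples = 5)
  fixed_private <- res$classified[res$classified$line_specific &
                                    res$classified$fixed &
                                    res$classified$line == "DUK", ]
  expect_equal(sort(unique(round(fixed_private$start, -4))), c(1e6, 5e6))
  shared <- res$classified[abs(res$classified$start - 9e6) < 2000, ]
  expect_true(all(!shared$line_specific))
})
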