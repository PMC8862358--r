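#' Neutral two-population drift-recovery experiment
#'
#' Simulates two populations of `n_pairs` breeding pairs (Wright-Fisher
#' random mating, unlinked sites, no selection, no bottleneck) drifting
#' independently from a shared outbred founder pool for `n_generations`
#' generations, then estimates the multi-locus Weir-Cockerham F_ST between
#' the two whole populations. Under pure drift the expectation is
#' `1 - (1 - 1/(2N))^t` with `2N` chromosomes per population.
#'
#' @param seed base seed; replicate r uses `seed * 100 + r`.
#' @param n_reps number of independent replicates (default 20).
#' @param n_pairs breeding pairs per population (default 25, i.e. 2N = 100).
#' @param n_generations generations of drift (default 50).
#' @param n_sites unlinked sites (default 2000).
#' @return list: `fst` per replicate, `mean`, `se` (of the replicate means),
#'   `expected`.
#' @export
drift_experiment <- function(seed, n_reps = 20, n_pairs = 25,
                             n_generations = 50, n_sites = 2000) {
  fst <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(seed = seed * 100 + r,
                      chrom_lengths = c(chr1 = 1e6), n_sites = n_sites,
                      founder_af = list(shape1 = 0.5, shape2 = 0.5),
                      n_inbred_strains = 0,
                      lines = data.frame(line = c("A", "B"),
                                         n_pairs = as.integer(n_pairs),
                                         selected = FALSE, prop_selected = 1,
                                         bottleneck_gen = 0L,
                                         bottleneck_pairs = as.integer(n_pairs)),
                      n_generations = n_generations, n_qtl = 1,
                      mating = "random", linked = FALSE, track_ancestry = FALSE,
                      n_sampled_high = n_pairs, n_sampled_low = n_pairs)
    sim <- simulate_dataset(cfg, emulate = FALSE, discovered_only = FALSE)
    fst_global(fst_sites(sim$g, sim$lm, "A", ref = "B", snps_only = FALSE))
  }, 0)
  list(fst = fst, mean = mean(fst), se = sd(fst) / sqrt(n_reps),
       expected = 1 - (1 - 1 / (4 * n_pairs))^n_generations)
}

rdd_hit <- function(regions, qtl) {
  nrow(regions) > 0 && any(regions$chrom == qtl$chrom &
                             regions$start <= qtl$pos & regions$end >= qtl$pos)
}

#' RDD sensitivity experiment: one large-effect selected QTL
#'
#' Runs the default six-line breeding design with a single large-effect QTL
#' (heritability 0.5) under truncation selection in the target line only (all
#' other lines drift neutrally), scans all contrasts against the control, and
#' asks whether a region of distinct differentiation overlapping the QTL is
#' detected.
#'
#' @param seed base seed.
#' @param n_reps replicates (default 10).
#' @param target target line (default `"DUK"`).
#' @param top_pct,bottom_pct RDD thresholds (defaults 95 / 10).
#' @return list: per-replicate `hit`, `n_rdd`, `qtl_final_af`, and the
#'   detection `rate`.
#' @export
rdd_sweep_experiment <- function(seed, n_reps = 10, target = "DUK",
                                 top_pct = 95, bottom_pct = 10) {
  hits <- logical(n_reps); n_rdd <- integer(n_reps); qaf <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    lines <- default_lines()
    lines$selected <- lines$line == target
    cfg <- sim_config(seed = seed * 100 + r, lines = lines, n_qtl = 1,
                      heritability = 0.5, qtl_min_maf = 0.2,
                      track_ancestry = FALSE)
    sim <- simulate_dataset(cfg, emulate = FALSE)
    ct <- fst_contrasts(sim$g, sim$lm)
    rdd <- detect_rdd(ct, target, top_pct = top_pct,
                      bottom_pct = bottom_pct, lm = sim$lm)
    hits[r] <- rdd_hit(rdd$regions, sim$truth$qtl)
    n_rdd[r] <- nrow(rdd$regions)
    qaf[r] <- sim$truth$trajectories[[target]][cfg$n_generations, 1]
  }
  list(hit = hits, n_rdd = n_rdd, qtl_final_af = qaf, rate = mean(hits))
}

#' RDD specificity experiment: fully neutral design
#'
#' Runs the default six-line design with selection disabled everywhere and
#' counts windows passing the RDD criterion for every target, comparing the
#' total against the chance expectation implied by the percentile thresholds
#' under independence (`top * bottom^k` for `k` other contrasts), and testing
#' qualifying windows for enrichment at the (now phenotypically inert) QTL
#' positions.
#'
#' @param seed base seed.
#' @param n_reps replicates (default 6).
#' @param top_pct,bottom_pct RDD thresholds.
#' @return list: `n_qualifying` (total qualifying windows), `n_trials`,
#'   `expected`, `binom_p` (test of count vs chance expectation),
#'   `qtl_overlap_p` (enrichment test, 1 when no qualifying windows),
#'   `per_target` counts.
#' @export
rdd_neutral_experiment <- function(seed, n_reps = 6, top_pct = 95,
                                   bottom_pct = 10) {
  tot_q <- 0L; tot_trials <- 0; tot_expected <- 0
  qtl_hits <- 0L; qtl_frac <- numeric(0)
  per_target <- c()
  for (r in seq_len(n_reps)) {
    lines <- default_lines()
    lines$selected <- FALSE
    cfg <- sim_config(seed = seed * 100 + r, lines = lines,
                      track_ancestry = FALSE)
    sim <- simulate_dataset(cfg, emulate = FALSE)
    ct <- fst_contrasts(sim$g, sim$lm)
    qtl_gr <- GenomicRanges::GRanges(sim$truth$qtl$chrom,
                                     IRanges::IRanges(sim$truth$qtl$pos, width = 1))
    for (tg in names(ct)) {
      rdd <- detect_rdd(ct, tg, top_pct = top_pct, bottom_pct = bottom_pct,
                        lm = sim$lm)
      k <- length(rdd$thresholds$others_used)
      nw <- nrow(ct[[tg]])
      nq <- nrow(rdd$windows)
      per_target[tg] <- sum(per_target[tg], nq, na.rm = TRUE)
      tot_q <- tot_q + nq
      tot_trials <- tot_trials + nw
      tot_expected <- tot_expected + nw * (1 - top_pct / 100) * (bottom_pct / 100)^k
      wgr <- GenomicRanges::GRanges(ct[[tg]]$chrom,
                                    IRanges::IRanges(ct[[tg]]$start, ct[[tg]]$end))
      qtl_frac <- c(qtl_frac,
                    mean(GenomicRanges::countOverlaps(wgr, qtl_gr) > 0))
      if (nq > 0) {
        qgr <- GenomicRanges::GRanges(rdd$windows$chrom,
                                      IRanges::IRanges(rdd$windows$start,
                                                       rdd$windows$end))
        qtl_hits <- qtl_hits + sum(GenomicRanges::countOverlaps(qgr, qtl_gr) > 0)
      }
    }
  }
  p_chance <- tot_expected / tot_trials
  binom_p <- stats::binom.test(tot_q, tot_trials, p_chance)$p.value
  qtl_overlap_p <- if (tot_q > 0)
    stats::binom.test(qtl_hits, tot_q, mean(qtl_frac))$p.value else 1
  list(n_qualifying = tot_q, n_trials = tot_trials, expected = tot_expected,
       binom_p = binom_p, qtl_overlap_p = qtl_overlap_p,
       per_target = per_target)
}

#' RoH recovery experiment on bottlenecked lines
#'
#' Simulates the control line plus two selected, bottlenecked lines of the
#' default design, emulates sequencing, calls RoH tracts with the HMM on the
#' high-coverage (24x) samples, and measures (a) the fraction of true
#' autozygous bases in tracts >= `min_tract` recovered by the calls and
#' (b) whether every selected line's mean RoH genome fraction exceeds the
#' control's.
#'
#' @param seed base seed.
#' @param n_reps replicates (default 8).
#' @param lines_idx rows of [default_lines()] to simulate (default control,
#'   DUK, DU6).
#' @param min_tract minimum true tract length measured (default 1 Mb).
#' @return list: `recall` (pooled across replicates), `ordering` (per
#'   replicate logical), `ordering_rate`, per-line mean fractions.
#' @export
roh_experiment <- function(seed, n_reps = 8, lines_idx = c(1, 2, 4),
                           min_tract = 1e6) {
  ov <- 0; tot <- 0
  ordering <- logical(n_reps)
  frac_sel <- numeric(0); frac_ctl <- numeric(0)
  for (r in seq_len(n_reps)) {
    lines <- default_lines()[lines_idx, ]
    cfg <- sim_config(seed = seed * 100 + r, lines = lines)
    sim <- simulate_dataset(cfg)
    hi <- names(sim$truth$coverage_set)[sim$truth$coverage_set == "high"]
    tracts <- call_roh(sim$g, sim$lm, samples = hi)
    tt <- sim$truth$tracts
    tt <- tt[tt$length >= min_tract & tt$sample %in% hi, ]
    for (i in seq_len(nrow(tt))) {
      ct <- tracts[tracts$sample == tt$sample[i] & tracts$chrom == tt$chrom[i], ]
      tot <- tot + tt$length[i]
      if (nrow(ct))
        ov <- ov + sum(pmax(0, pmin(ct$end, tt$end[i]) -
                              pmax(ct$start, tt$start[i])))
    }
    summ <- roh_summary(tracts, cfg$chrom_lengths)
    pl <- summ$per_line
    ctl <- pl$total[pl$line == "FZTDU"]
    sel <- pl$total[pl$line != "FZTDU"]
    ordering[r] <- all(sel > ctl)
    frac_sel <- c(frac_sel, sel); frac_ctl <- c(frac_ctl, ctl)
  }
  list(recall = ov / tot, ordering = ordering,
       ordering_rate = mean(ordering),
       mean_fraction_selected = mean(frac_sel),
       mean_fraction_control = mean(frac_ctl))
}

#' LD decay experiment: bottlenecked line vs control
#'
#' Simulates the control line and one selected, bottlenecked line of the
#' default design, thins sites to >= 100 kb, computes pairwise r2 within
#' 5 Mb per line and the distance-binned decay curves.
#'
#' @param seed seed.
#' @param lines_idx rows of [default_lines()] (default control and DUK).
#' @param min_pairs bins with fewer pairs in either line are dropped from
#'   the comparison summaries (default 50).
#' @return list: `curves` (per line), `n_pairs` per line, `ordering_frac`
#'   (fraction of compared bins where the bottlenecked line's mean r2 is at
#'   least the control's), `max_increase` (largest adjacent-bin increase of
#'   the control curve), `spearman` (rank correlation of control mean r2
#'   with distance).
#' @export
ld_experiment <- function(seed, lines_idx = c(1, 2), min_pairs = 50) {
  lines <- default_lines()[lines_idx, ]
  # larger, sparser genome: LD pairs need 100-kb thinning over many Mb, not
  # the window-scan's dense SNP spacing
  cfg <- sim_config(seed = seed, lines = lines, track_ancestry = FALSE,
                    chrom_lengths = setNames(rep(4e7, 6), paste0("chr", 1:6)),
                    n_sites = 9600)
  sim <- simulate_dataset(cfg, emulate = FALSE)
  thin <- thin_sites(sim$g)
  gt <- subset_sites(sim$g, thin)
  curves <- list(); npairs <- c()
  for (ln in lines$line) {
    pr <- ld_r2(gt, sim$lm, ln)
    curves[[ln]] <- decay_curve(pr)
    npairs[ln] <- nrow(pr)
  }
  ctl <- curves[[lines$line[1]]]
  sel <- curves[[lines$line[2]]]
  ok <- ctl$n_pairs >= min_pairs & sel$n_pairs >= min_pairs
  ordering_frac <- mean(sel$mean_r2[ok] >= ctl$mean_r2[ok])
  cm <- ctl$mean_r2[ok]
  list(curves = curves, n_pairs = npairs, ordering_frac = ordering_frac,
       max_increase = max(diff(cm)),
       spearman = suppressWarnings(cor(ctl$bin_mid[ok], cm,
                                       method = "spearman")))
}
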