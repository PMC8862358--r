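#' Configuration for the forward breeding-design simulator
#'
#' Describes a multi-line selective-breeding design: an admixed founder pool
#' created by crossing outbred and inbred strains, a set of lines bred as
#' monogamous pairs with (optional) truncation selection on a polygenic trait,
#' a relocation bottleneck re-founding each line from a handful of random
#' pairs, and a sequencing-depth emulator producing genotype likelihoods at
#' two coverage regimes.
#'
#' The default `lines` table mirrors the breeding history of a six-line mouse
#' selection experiment: one large unselected control (200 breeding pairs) and
#' five trait-selected lines of 60-100 pairs with per-line selected
#' proportions, all relocated around generation 160 through a severe
#' bottleneck (7-55 surviving pairs), with individuals sampled at generation
#' 188. Genome size and site count are desk-scale (three 20-Mb autosomes)
#' while keeping realistic SNP density for 50-kb window statistics.
#'
#' @param seed integer seed; mandatory, every simulation is reproducible.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_sites total number of candidate variant sites.
#' @param founder_af list describing the founder allele-frequency spectrum:
#'   either `list(shape1=, shape2=)` for a Beta spectrum or
#'   `list(constant=p)`.
#' @param n_founder_strains,n_inbred_strains,founders_per_strain founder pool
#'   composition; the last `n_inbred_strains` strains are fully inbred (one
#'   haplotype per strain, carried homozygously by its founders).
#' @param lines data.frame with columns `line`, `n_pairs`, `selected`,
#'   `prop_selected`, `bottleneck_gen`, `bottleneck_pairs`.
#' @param n_generations number of discrete non-overlapping generations.
#' @param n_qtl,qtl_effect_sd,qtl_min_maf polygenic trait architecture: QTL
#'   count, Normal effect-size sd, and minimum founder minor-allele frequency
#'   for a site to be eligible as QTL.
#' @param heritability narrow-sense h2 of the trait in the founder pool; sets
#'   the environmental noise sd.
#' @param recomb_rate_cM_per_Mb constant recombination rate (default 0.51,
#'   the mouse genome average).
#' @param mating `"pairs"` for monogamous breeding pairs with balanced
#'   litters, `"random"` for Wright-Fisher random union of gametes (used for
#'   neutral drift experiments).
#' @param linked simulate crossovers along chromosomes (`TRUE`) or treat all
#'   sites as unlinked (`FALSE`).
#' @param track_ancestry carry founder-haplotype ancestry labels through the
#'   pedigree so true autozygous tracts can be derived (default TRUE; disable
#'   to halve memory traffic when tracts are not needed).
#' @param segregating_only drop sites monomorphic in the founder pool.
#' @param n_sampled_high,n_sampled_low samples per line assigned to the high
#'   and low coverage regimes at the final generation.
#' @param depth_mean named vector of mean depths for the two coverage sets
#'   (default `c(high = 24, low = 8)`, the realized coverages of a 30x/5x
#'   sequencing design).
#' @param base_error_rate per-read base error rate used by the sequencing
#'   emulator.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7),
                       n_sites = 24000,
                       founder_af = list(shape1 = 0.5, shape2 = 0.5),
                       n_founder_strains = 8,
                       n_inbred_strains = 4,
                       founders_per_strain = 8,
                       lines = default_lines(),
                       n_generations = 188,
                       n_qtl = 100,
                       qtl_effect_sd = 1,
                       qtl_min_maf = 0.05,
                       heritability = 0.3,
                       recomb_rate_cM_per_Mb = 0.51,
                       mating = c("pairs", "random"),
                       linked = TRUE,
                       track_ancestry = TRUE,
                       segregating_only = TRUE,
                       n_sampled_high = 10,
                       n_sampled_low = 15,
                       depth_mean = c(high = 24, low = 8),
                       base_error_rate = 1e-3) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  mating <- match.arg(mating)
  stopifnot(is.data.frame(lines),
            all(c("line", "n_pairs", "selected", "prop_selected",
                  "bottleneck_gen", "bottleneck_pairs") %in% names(lines)),
            all(lines$prop_selected > 0 & lines$prop_selected <= 1),
            all(lines$n_pairs >= 1), n_generations >= 1, n_sites >= 1,
            n_inbred_strains <= n_founder_strains)
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_sites = n_sites, founder_af = founder_af,
              n_founder_strains = n_founder_strains,
              n_inbred_strains = n_inbred_strains,
              founders_per_strain = founders_per_strain,
              lines = lines, n_generations = n_generations, n_qtl = n_qtl,
              qtl_effect_sd = qtl_effect_sd, qtl_min_maf = qtl_min_maf,
              heritability = heritability,
              recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
              mating = mating, linked = linked,
              track_ancestry = track_ancestry,
              segregating_only = segregating_only,
              n_sampled_high = n_sampled_high, n_sampled_low = n_sampled_low,
              depth_mean = depth_mean, base_error_rate = base_error_rate)
  class(cfg) <- "sim_config"
  cfg
}

#' Default six-line breeding design table
#'
#' One unselected control and five trait-selected lines, with breeding-pair
#' numbers, selected proportions and relocation-bottleneck sizes matching a
#' long-term mouse selection experiment (control: 200 pairs, bottleneck 55;
#' selected lines: 60-100 pairs, bottlenecks of 7-24 pairs at generation 160).
#' @return data.frame usable as the `lines` argument of [sim_config()].
#' @export
default_lines <- function() {
  data.frame(
    line = c("FZTDU", "DUK", "DUC", "DU6", "DU6P", "DUhLB"),
    n_pairs = c(200L, 60L, 60L, 80L, 80L, 100L),
    selected = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    prop_selected = c(1, 0.5, 0.5, 0.65, 0.55, 0.7),
    bottleneck_gen = c(160L, 160L, 160L, 160L, 160L, 160L),
    bottleneck_pairs = c(55L, 19L, 24L, 7L, 19L, 22L),
    stringsAsFactors = FALSE
  )
}

#' Simulate the admixed founder haplotype pool
#'
#' Draws per-site ancestral allele frequencies from the configured spectrum,
#' then builds the pool by crossing outbred strains (independent Bernoulli
#' haplotypes) and fully inbred strains (a single strain haplotype carried
#' homozygously). Every founder haplotype receives a distinct ancestry label
#' (inbred strains share one label) used downstream to derive true autozygous
#' tracts.
#'
#' @param cfg a [sim_config()].
#' @return A `founder_pool` list: `haps`/`anc` raw matrices (2*individuals x
#'   sites), `sites` data.frame, drawn spectrum frequencies `p_drawn`, realized
#'   pool frequencies `af_pool`, QTL table `qtl`, and map helpers.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_sites < cfg$n_qtl) stop("n_sites must be >= n_qtl")
  chroms <- names(cfg$chrom_lengths)
  n_per <- round(cfg$n_sites * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  pos <- integer(0); chrom <- character(0)
  for (i in seq_along(chroms)) {
    p <- sort(sample.int(cfg$chrom_lengths[[i]], n_per[[i]]))
    pos <- c(pos, p); chrom <- c(chrom, rep(chroms[i], n_per[[i]]))
  }
  S <- length(pos)
  p0 <- if (!is.null(cfg$founder_af$constant)) {
    rep(cfg$founder_af$constant, S)
  } else {
    rbeta(S, cfg$founder_af$shape1, cfg$founder_af$shape2)
  }

  n_out <- cfg$n_founder_strains - cfg$n_inbred_strains
  F_ind <- cfg$n_founder_strains * cfg$founders_per_strain
  # sites x haplotypes; columns 2i-1, 2i are the two haplotypes of founder i
  haps <- matrix(as.raw(0), S, 2L * F_ind)
  anc <- matrix(as.raw(0), S, 2L * F_ind)
  lab <- 0L
  col <- 1L
  for (st in seq_len(cfg$n_founder_strains)) {
    inbred <- st > n_out
    strain_hap <- if (inbred) as.raw(rbinom(S, 1L, p0)) else NULL
    if (inbred) lab <- lab + 1L
    for (ind in seq_len(cfg$founders_per_strain)) {
      for (cpy in 1:2) {
        if (inbred) {
          haps[, col] <- strain_hap
          anc[, col] <- as.raw(lab)
        } else {
          lab <- lab + 1L
          haps[, col] <- as.raw(rbinom(S, 1L, p0))
          anc[, col] <- as.raw(lab)
        }
        col <- col + 1L
      }
    }
  }
  if (lab > 255L) stop("founder pool too large for raw ancestry labels")

  af_pool <- rowMeans(matrix(as.integer(haps), nrow(haps)))
  keep <- if (cfg$segregating_only) which(af_pool > 0 & af_pool < 1) else seq_len(S)
  haps <- haps[keep, , drop = FALSE]
  anc <- anc[keep, , drop = FALSE]
  sites <- data.frame(chrom = chrom[keep], pos = pos[keep],
                      stringsAsFactors = FALSE)
  af_pool <- af_pool[keep]
  p_drawn <- p0[keep]

  maf <- pmin(af_pool, 1 - af_pool)
  eligible <- which(maf >= cfg$qtl_min_maf)
  if (length(eligible) < cfg$n_qtl)
    stop("not enough segregating sites for the requested number of QTL")
  qtl_idx <- sort(sample(eligible, cfg$n_qtl))
  qtl <- data.frame(site = qtl_idx, chrom = sites$chrom[qtl_idx],
                    pos = sites$pos[qtl_idx],
                    effect = rnorm(cfg$n_qtl, 0, cfg$qtl_effect_sd),
                    founder_af = af_pool[qtl_idx])

  morgan_per_bp <- cfg$recomb_rate_cM_per_Mb / 1e6 / 100
  chrom_start <- c(0L, cumsum(as.integer(table(factor(sites$chrom, levels = chroms)))))
  pool <- list(haps = haps, anc = anc, sites = sites, p_drawn = p_drawn,
               af_pool = af_pool, qtl = qtl,
               cm = sites$pos * morgan_per_bp,
               chrom_start = chrom_start,
               chrom_len_morgan = unname(cfg$chrom_lengths * morgan_per_bp),
               chroms = chroms)
  class(pool) <- "founder_pool"
  pool
}

# dosage (sites x individuals) of individuals `inds` (1-based), optionally
# restricted to site rows `site_idx`
ind_dosage <- function(haps, inds = NULL, site_idx = NULL) {
  h <- if (is.null(site_idx)) haps else haps[site_idx, , drop = FALSE]
  if (is.null(inds)) inds <- seq_len(ncol(h) %/% 2L)
  cpp_dosage(h, as.integer(inds) - 1L)
}

hap_cols <- function(inds) as.vector(rbind(2L * inds - 1L, 2L * inds))

#' Breed the configured lines forward in time
#'
#' Each line starts from individuals drawn from the founder pool and advances
#' through discrete generations. Under `mating = "pairs"`, parents form
#' monogamous pairs with balanced litters (litter size is set automatically so
#' the next generation can be filled after truncation selection); under
#' `mating = "random"` every gamete comes from a uniformly drawn parent
#' (Wright-Fisher). Selected lines rank candidates by trait value (QTL
#' genotypic value plus Normal environmental noise calibrated to the
#' configured heritability in the founder pool) and keep the top
#' `prop_selected`; the control and relocation-bottleneck generations pick
#' parents at random. At `bottleneck_gen` the line is refounded from
#' `bottleneck_pairs` random pairs.
#'
#' @param pool a `founder_pool` from [simulate_founders()].
#' @param cfg the same [sim_config()].
#' @return A `sim_result` list with per-line sampled haplotypes/dosages and a
#'   `truth` component (QTL table, per-generation QTL allele-frequency
#'   trajectories, pedigree of retained parents, true autozygous tracts of the
#'   sampled individuals, environmental sd per line).
#' @export
breed <- function(pool, cfg) {
  stopifnot(inherits(pool, "founder_pool"), inherits(cfg, "sim_config"))
  S <- nrow(pool$sites)
  n_sample <- cfg$n_sampled_high + cfg$n_sampled_low
  eff <- pool$qtl$effect
  qtl_site_rows <- pool$qtl$site

  gv_pool <- as.numeric(crossprod(ind_dosage(pool$haps, site_idx = qtl_site_rows), eff))
  v_g <- var(gv_pool)
  sigma_e <- if (is.finite(v_g) && v_g > 0 && cfg$heritability < 1) {
    sqrt(v_g * (1 - cfg$heritability) / cfg$heritability)
  } else 1

  lines_out <- list()
  traj <- list()
  ped <- list()
  pool_inds <- ncol(pool$haps) %/% 2L
  track <- isTRUE(cfg$track_ancestry)

  for (li in seq_len(nrow(cfg$lines))) {
    ln <- cfg$lines[li, ]
    P <- ln$n_pairs
    init <- sample.int(pool_inds, 2L * P, replace = TRUE)
    cur_h <- cpp_subset_cols(pool$haps, hap_cols(init) - 1L)
    cur_a <- if (track) cpp_subset_cols(pool$anc, hap_cols(init) - 1L) else cur_h
    n_par <- 2L * P
    line_traj <- matrix(NA_real_, cfg$n_generations, nrow(pool$qtl))
    line_ped <- vector("list", cfg$n_generations)
    off_h <- NULL; off_a <- NULL

    for (g in seq_len(cfg$n_generations)) {
      P_g <- n_par %/% 2L
      bottleneck_next <- (g + 1L) == ln$bottleneck_gen
      P_next <- if (bottleneck_next) ln$bottleneck_pairs else ln$n_pairs
      random_choice <- !ln$selected || bottleneck_next
      prop <- if (random_choice) 1 else ln$prop_selected
      needed <- if (g == cfg$n_generations) max(n_sample, 2L * P_next) else 2L * P_next
      litter <- max(2L, ceiling(needed / prop / P_g))
      n_off <- litter * P_g

      if (cfg$mating == "random") {
        fathers <- sample.int(P_g * 2L, n_off, replace = TRUE)
        mothers <- sample.int(P_g * 2L, n_off, replace = TRUE)
        pair_of <- rep(NA_integer_, n_off)
      } else {
        perm <- sample.int(2L * P_g)
        fa <- perm[seq_len(P_g)]
        mo <- perm[P_g + seq_len(P_g)]
        pair_of <- rep(seq_len(P_g), litter)[seq_len(n_off)]
        fathers <- fa[pair_of]
        mothers <- mo[pair_of]
      }
      par_vec <- as.vector(rbind(fathers, mothers)) - 1L
      gam <- cpp_make_gametes(cur_h, cur_a, par_vec, pool$chrom_start,
                              pool$cm, pool$chrom_len_morgan, cfg$linked, track)
      off_h <- gam$haps
      off_a <- if (track) gam$anc else off_h

      dos_q <- ind_dosage(off_h, site_idx = qtl_site_rows)
      line_traj[g, ] <- rowMeans(dos_q) / 2

      if (g == cfg$n_generations) {
        line_ped[[g]] <- data.frame(gen = g, chosen = NA_integer_,
                                    pair = NA_integer_)[0, ]
        break
      }
      if (random_choice) {
        chosen <- sample.int(n_off, needed)
      } else {
        trait <- as.numeric(crossprod(dos_q, eff)) + rnorm(n_off, 0, sigma_e)
        n_sel <- max(needed, round(prop * n_off))
        sel_pool <- order(trait, decreasing = TRUE)[seq_len(n_sel)]
        chosen <- if (n_sel == needed) sel_pool else sample(sel_pool, needed)
      }
      line_ped[[g]] <- data.frame(gen = g, chosen = chosen, pair = pair_of[chosen])
      cur_h <- cpp_subset_cols(off_h, hap_cols(chosen) - 1L)
      cur_a <- if (track) cpp_subset_cols(off_a, hap_cols(chosen) - 1L) else cur_h
      n_par <- needed
    }

    n_off_final <- ncol(off_h) %/% 2L
    if (n_off_final < n_sample) stop("line ", ln$line, ": final pool smaller than sample size")
    pick <- sort(sample.int(n_off_final, n_sample))
    smp_h <- cpp_subset_cols(off_h, hap_cols(pick) - 1L)
    smp_a <- if (track) cpp_subset_cols(off_a, hap_cols(pick) - 1L) else NULL
    sample_names <- sprintf("%s_%02d", ln$line, seq_len(n_sample))
    lines_out[[ln$line]] <- list(haps = smp_h, anc = smp_a,
                                 gt = ind_dosage(smp_h),
                                 samples = sample_names)
    traj[[ln$line]] <- line_traj
    ped[[ln$line]] <- do.call(rbind, line_ped)
  }

  truth <- list(qtl = pool$qtl, trajectories = traj, pedigree = ped,
                sigma_e = sigma_e,
                tracts = if (track) true_autozygous_tracts(lines_out, pool$sites) else NULL)
  structure(list(lines = lines_out, truth = truth, sites = pool$sites,
                 chroms = pool$chroms), class = "sim_result")
}

#' True autozygous tracts of sampled individuals
#'
#' A segment is autozygous when the two haplotypes of an individual descend
#' from the same founder haplotype; tracts are maximal runs of sites with
#' equal ancestry labels, reported as 1-based inclusive bp intervals.
#'
#' @param lines_out per-line sampled haplotype/ancestry matrices.
#' @param sites site table (chrom, pos).
#' @return data.frame: line, sample, chrom, start, end, n_sites, length.
#' @keywords internal
true_autozygous_tracts <- function(lines_out, sites) {
  res <- list()
  chroms <- unique(sites$chrom)
  for (ln in names(lines_out)) {
    x <- lines_out[[ln]]
    n_ind <- ncol(x$haps) %/% 2L
    for (i in seq_len(n_ind)) {
      a1 <- x$anc[, 2L * i - 1L]
      a2 <- x$anc[, 2L * i]
      eq <- a1 == a2
      for (ch in chroms) {
        idx <- which(sites$chrom == ch)
        if (!length(idx)) next
        r <- rle(eq[idx])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        w <- which(r$values)
        if (!length(w)) next
        res[[length(res) + 1L]] <- data.frame(
          line = ln, sample = x$samples[i], chrom = ch,
          start = sites$pos[idx[starts[w]]], end = sites$pos[idx[ends[w]]],
          n_sites = r$lengths[w])
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(line = character(), sample = character(), chrom = character(),
               start = integer(), end = integer(), n_sites = integer())
  out$length <- out$end - out$start
  out
}

#' Emulate short-read sequencing of known genotypes
#'
#' Per genotype cell, read depth is Poisson with the sample's mean depth; alt
#' read counts are Binomial given the true dosage and the base error rate;
#' phred-scaled genotype likelihoods follow from the binomial read-count
#' likelihoods of the three genotypes (capped at 255), GQ is the
#' second-smallest PL, and the called dosage is the PL-minimizing genotype
#' (missing when depth is 0).
#'
#' @param gt_true sites x samples integer matrix of true dosages (0/1/2).
#' @param sites site table with chrom, pos (ref/alt filled in as A/T dummies
#'   if absent).
#' @param samples sample names.
#' @param depth_mean per-sample mean depth (recycled).
#' @param base_error_rate per-read error rate.
#' @param chrom_lengths optional, forwarded to [genotype_data()].
#' @return A `genotype_data` with gt/dp/gq/pl filled.
#' @export
sequence_emulator <- function(gt_true, sites, samples, depth_mean,
                              base_error_rate = 1e-3, chrom_lengths = NULL) {
  gt_true <- as.matrix(gt_true)
  ns <- nrow(gt_true); nsmp <- ncol(gt_true)
  stopifnot(all(gt_true %in% 0:2))
  depth_mean <- rep_len(depth_mean, nsmp)
  dp <- matrix(rpois(ns * nsmp, rep(depth_mean, each = ns)), ns, nsmp)
  e <- base_error_rate
  p_alt <- e + (gt_true / 2) * (1 - 2 * e)
  alt <- matrix(rbinom(ns * nsmp, as.vector(dp), as.vector(p_alt)), ns, nsmp)
  l10 <- function(p) dbinom(as.vector(alt), as.vector(dp), p, log = TRUE) / log(10)
  ll <- cbind(l10(e), l10(0.5), l10(1 - e))
  ll[!is.finite(ll)] <- -1e6
  mx <- pmax(ll[, 1], ll[, 2], ll[, 3])
  pl <- round(-10 * (ll - mx))
  pl <- pmin(pl, 255)
  call <- max.col(-pl, ties.method = "first") - 1L
  call[dp == 0] <- NA_integer_
  # second-smallest PL; the smallest is 0 by construction
  gq <- pl[, 1] + pl[, 2] + pl[, 3] - pmax(pl[, 1], pl[, 2], pl[, 3])
  gq[dp == 0] <- 0
  if (is.null(sites$ref)) { sites$ref <- "A"; sites$alt <- "T" }
  genotype_data(sites, samples,
                gt = matrix(call, ns, nsmp),
                dp = dp,
                gq = matrix(gq, ns, nsmp),
                pl = list(RR = matrix(pl[, 1], ns, nsmp),
                          RA = matrix(pl[, 2], ns, nsmp),
                          AA = matrix(pl[, 3], ns, nsmp)),
                chrom_lengths = chrom_lengths)
}

#' Run the full simulator: founders, breeding, sequencing emulation
#'
#' @param cfg a [sim_config()].
#' @param emulate run the sequencing emulator (default TRUE); when FALSE the
#'   returned `genotype_data` carries the true dosages with no dp/gq/pl.
#' @param discovered_only keep only sites with at least one called alt allele
#'   across all samples (emulating variant discovery); default TRUE.
#' @return list: `g` (a `genotype_data`), `lm` (a `line_map` with a FERT
#'   pseudo-line when both DUK and DUC are present), `truth` (simulator ground
#'   truth incl. true dosage matrix `gt_true` and coverage-set assignment).
#' @export
simulate_dataset <- function(cfg, emulate = TRUE, discovered_only = TRUE) {
  set.seed(cfg$seed)
  pool <- simulate_founders(cfg)
  res <- breed(pool, cfg)

  gt_true <- do.call(cbind, lapply(res$lines, function(x) x$gt))
  samples <- unlist(lapply(res$lines, function(x) x$samples), use.names = FALSE)
  colnames(gt_true) <- samples
  assignment <- setNames(rep(cfg$lines$line,
                             each = cfg$n_sampled_high + cfg$n_sampled_low), samples)
  pseudo <- if (all(c("DUK", "DUC") %in% cfg$lines$line))
    list(FERT = c("DUK", "DUC")) else list()
  lm <- line_map(assignment, pseudo_lines = pseudo)
  coverage <- rep(rep(c("high", "low"), c(cfg$n_sampled_high, cfg$n_sampled_low)),
                  nrow(cfg$lines))
  names(coverage) <- samples

  sites <- res$sites
  sites$ref <- "A"; sites$alt <- "T"
  if (emulate) {
    depth <- cfg$depth_mean[coverage]
    g <- sequence_emulator(gt_true, sites, samples, depth,
                           base_error_rate = cfg$base_error_rate,
                           chrom_lengths = cfg$chrom_lengths)
  } else {
    g <- genotype_data(sites, samples, gt = gt_true,
                       chrom_lengths = cfg$chrom_lengths)
  }
  if (discovered_only) {
    keep <- rowSums(g$gt, na.rm = TRUE) >= 1
    g <- subset_sites(g, keep)
    res$truth$site_kept <- keep
    gt_true <- gt_true[keep, , drop = FALSE]
  }
  g <- log_step(g, "simulate_dataset", seed = cfg$seed,
                n_sites = nrow(g$sites), emulated = emulate)
  res$truth$gt_true <- gt_true
  res$truth$coverage_set <- coverage
  list(g = g, lm = lm, truth = res$truth, cfg = cfg)
}

#' Generate synthetic multi-caller structural-variant records
#'
#' Produces per-sample, per-caller SV records in the layout expected by the
#' SV consensus pipeline: each planted SV is reported by a configurable set of
#' callers for each carrier sample with breakpoint jitter, well-supported
#' quality fields, and the sample's coverage-set label. Random background
#' records (single-caller noise) can be added.
#'
#' @param planted data.frame: chrom, start, end, svtype, plus `lines` (comma
#'   separated carrier lines or `"all"`) and `fixed` (logical: carried
#'   homozygously by every sample of the carrier lines).
#' @param lm a `line_map`.
#' @param coverage_set named character vector (sample -> "high"/"low").
#' @param callers callers reporting each planted SV.
#' @param jitter_sd sd of Normal breakpoint jitter per record (bp).
#' @param n_background random single-caller noise records.
#' @param chrom_lengths used to place background records.
#' @return data.frame of SV records (one row per sample x caller x SV).
#' @export
simulate_sv_records <- function(planted, lm, coverage_set,
                                callers = c("manta", "whamg", "lumpy"),
                                jitter_sd = 100, n_background = 0,
                                chrom_lengths = NULL) {
  recs <- list()
  for (i in seq_len(nrow(planted))) {
    pv <- planted[i, ]
    carrier_lines <- if (identical(pv$lines, "all")) lm$lines else
      strsplit(pv$lines, ",", fixed = TRUE)[[1]]
    carriers <- unlist(lapply(carrier_lines, line_samples, lm = lm))
    if (!isTRUE(pv$fixed)) carriers <- carriers[seq_len(ceiling(length(carriers) / 2))]
    for (smp in carriers) {
      for (cl in callers) {
        js <- round(rnorm(1, 0, jitter_sd)); je <- round(rnorm(1, 0, jitter_sd))
        recs[[length(recs) + 1L]] <- data.frame(
          sample = smp, line = unname(lm$assignment[smp]),
          coverage_set = unname(coverage_set[smp]), caller = cl,
          svtype = pv$svtype, chrom = pv$chrom,
          start = max(1, pv$start + js), end = pv$end + je,
          gt = if (isTRUE(pv$fixed)) "hom" else sample(c("het", "hom"), 1),
          gq = 60, mapq = 60, su = 10, depth = 20, depth_ratio = 1,
          cross_chrom_fraction = 0)
      }
    }
  }
  if (n_background > 0) {
    stopifnot(!is.null(chrom_lengths))
    smps <- names(lm$assignment)
    for (b in seq_len(n_background)) {
      ch <- sample(names(chrom_lengths), 1)
      st <- sample.int(chrom_lengths[[ch]] - 1e5, 1)
      ln <- sample.int(50000, 1) + 50
      smp <- sample(smps, 1)
      recs[[length(recs) + 1L]] <- data.frame(
        sample = smp, line = unname(lm$assignment[smp]),
        coverage_set = unname(coverage_set[smp]),
        caller = sample(callers, 1),
        svtype = sample(c("DEL", "DUP", "INV"), 1), chrom = ch,
        start = st, end = st + ln, gt = "het", gq = 50, mapq = 55, su = 7,
        depth = 15, depth_ratio = 1, cross_chrom_fraction = 0)
    }
  }
  out <- do.call(rbind, recs)
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}
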