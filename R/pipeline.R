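#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; see [run_pipeline()] for the recognized blocks.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates: (optional) simulation, genotype/site filtering, per-line
#' allele-frequency summaries, F_ST window scans and RDD detection, windowed
#' nucleotide diversity, LD decay, RoH calling, and (optional) SV consensus
#' filtering. Stages communicate through files in `out_dir`; every stage's
#' parameters and outputs are recorded in a JSON manifest, and an identical
#' configuration plus seed reproduces identical outputs.
#'
#' Config blocks (all optional unless noted): `seed`; either `simulate`
#' (fields forwarded to [sim_config()]) or `vcf` + `line_map` paths; `filter`
#' (`dp_min`, `dp_sd_mult`, `gq_min`, `min_support`, `overrides`);
#' `windows` (`size`, `step`, `min_snps`); `rdd` (`top_pct`, `bottom_pct`);
#' `ld` (`min_dist`, `max_dist`, `bin_width`); `roh` (model parameters);
#' `sv_records` (TSV path) with `sv` thresholds; `gff` gene models;
#' `reference_line` (default FZTDU).
#'
#' @param config a list (see above) or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run (default all applicable).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir,
                         stages = c("simulate", "filter", "popstats", "fst",
                                    "rdd", "pi", "ld", "roh", "svmerge")) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  manifest <- list(package = "lineselect",
                   version = as.character(utils::packageVersion("lineselect")),
                   seed = seed, stages = list())
  tsv <- function(d, name) {
    p <- file.path(out_dir, name)
    write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  done <- function(name, params, outputs) {
    manifest$stages[[name]] <<- list(params = params, outputs = outputs)
  }
  ref <- config$reference_line %||% "FZTDU"
  w <- do.call(window_spec, config$windows %||% list())

  # --- inputs: simulate or read ------------------------------------------
  if ("simulate" %in% stages && !is.null(config$simulate)) {
    sargs <- config$simulate
    # YAML delivers lists; sim_config wants vectors / a data.frame
    if (!is.null(sargs$chrom_lengths)) sargs$chrom_lengths <- unlist(sargs$chrom_lengths)
    if (!is.null(sargs$depth_mean)) sargs$depth_mean <- unlist(sargs$depth_mean)
    if (!is.null(sargs$lines) && !is.data.frame(sargs$lines))
      sargs$lines <- as.data.frame(sargs$lines, stringsAsFactors = FALSE)
    scfg <- do.call(sim_config, c(sargs, list(seed = seed)))
    sim <- simulate_dataset(scfg)
    g <- sim$g; lmap <- sim$lm
    vcf_path <- file.path(out_dir, "simulated.vcf")
    write_vcf(g, vcf_path)
    lm_path <- write_line_map(lmap, file.path(out_dir, "line_map.tsv"))
    truth_path <- file.path(out_dir, "sim_truth.json")
    jsonlite::write_json(list(qtl = sim$truth$qtl,
                              tracts = sim$truth$tracts),
                         truth_path, digits = NA)
    done("simulate", config$simulate, c(vcf_path, lm_path, truth_path))
  } else {
    if (is.null(config$vcf) || is.null(config$line_map))
      stop("either a simulate block or vcf + line_map paths are required")
    g <- read_vcf(config$vcf)
    lmap <- read_line_map(config$line_map,
                          pseudo_lines = config$pseudo_lines %||% list())
  }

  # --- filter ------------------------------------------------------------
  if ("filter" %in% stages) {
    fp <- config$filter %||% list()
    if (!is.null(g$dp) && !is.null(g$gq))
      g <- apply_genotype_filters(g, dp_min = fp$dp_min %||% 4,
                                  dp_sd_mult = fp$dp_sd_mult %||% 3,
                                  gq_min = fp$gq_min %||% 20)
    g <- site_support_filter(g, lmap, min_support = fp$min_support %||% 15,
                             overrides = unlist(fp$overrides %||% c(DU6 = 12)))
    if (!is.null(config$microsatellites))
      g <- exclude_intervals(g, read_bed_track(config$microsatellites))
    filt_vcf <- file.path(out_dir, "filtered.vcf")
    write_vcf(g, filt_vcf)
    rep_path <- write_filter_report(g, file.path(out_dir, "filter_report.json"))
    done("filter", fp, c(filt_vcf, rep_path))
  }

  # --- population statistics --------------------------------------------
  if ("popstats" %in% stages) {
    af <- line_allele_frequencies(g, lmap)
    cls <- classify_sites(af)
    cls_counts <- as.data.frame.matrix(
      t(sapply(colnames(cls), function(ln) table(factor(cls[, ln],
        levels = c("fixed_ref", "fixed_alt", "polymorphic", "uncalled"))))))
    cls_counts <- cbind(line = rownames(cls_counts), cls_counts)
    sets <- shared_private_sets(af, control = intersect(ref, lmap$lines))
    sets_df <- data.frame(line = names(sets$totals), total = sets$totals,
                          private = sets$private)
    if (!is.null(sets$shared_with_control))
      sets_df$shared_with_control <- sets$shared_with_control
    vs <- variant_summary(g)
    outs <- c(tsv(cls_counts, "site_classification.tsv"),
              tsv(sets_df, "shared_private.tsv"),
              tsv(data.frame(type = names(vs$counts), count = vs$counts),
                  "variant_counts.tsv"))
    done("popstats", list(), outs)
  }

  # --- FST scans and RDDs -----------------------------------------------
  contrasts <- NULL
  if (any(c("fst", "rdd") %in% stages)) {
    contrasts <- fst_contrasts(g, lmap, ref = ref, w = w)
  }
  if ("fst" %in% stages) {
    outs <- character(0)
    for (tg in names(contrasts))
      outs <- c(outs, tsv(contrasts[[tg]], sprintf("fst_windows_%s.tsv", tg)))
    gw <- genomewide_mean_fst(g, lmap, w = w)
    outs <- c(outs, tsv(cbind(line = rownames(gw), as.data.frame(gw)),
                        "fst_genomewide_matrix.tsv"))
    done("fst", list(windows = unclass(w), reference = ref), outs)
  }
  if ("rdd" %in% stages && length(contrasts) >= 2) {
    rp <- config$rdd %||% list()
    genes <- if (!is.null(config$gff)) config$gff else NULL
    outs <- character(0)
    for (tg in names(contrasts)) {
      rdd <- detect_rdd(contrasts, tg, top_pct = rp$top_pct %||% 95,
                        bottom_pct = rp$bottom_pct %||% 10, lm = lmap)
      reg <- rdd$regions
      if (!is.null(genes)) reg <- annotate_regions(reg, genes)
      outs <- c(outs, tsv(reg, sprintf("rdd_%s.tsv", tg)))
    }
    done("rdd", rp, outs)
  }

  # --- nucleotide diversity ---------------------------------------------
  if ("pi" %in% stages) {
    pi_w <- nucleotide_diversity_windows(g, lmap, w)
    done("pi", list(windows = unclass(w)), tsv(pi_w, "pi_windows.tsv"))
  }

  # --- LD decay ----------------------------------------------------------
  if ("ld" %in% stages) {
    lp <- config$ld %||% list()
    thin <- thin_sites(g, min_dist = lp$min_dist %||% 1e5)
    gt_thin <- subset_sites(g, thin)
    outs <- character(0)
    for (ln in lmap$lines) {
      pr <- ld_r2(gt_thin, lmap, ln, max_dist = lp$max_dist %||% 5e6)
      dc <- decay_curve(pr, bin_width = lp$bin_width %||% 1e5,
                        min_dist = lp$min_dist %||% 1e5,
                        max_dist = lp$max_dist %||% 5e6)
      dc$line <- ln
      outs <- c(outs, tsv(dc, sprintf("ld_decay_%s.tsv", ln)))
    }
    done("ld", lp, outs)
  }

  # --- runs of homozygosity ---------------------------------------------
  if ("roh" %in% stages && !is.null(g$pl)) {
    model <- do.call(roh_model, config$roh %||% list())
    tracts <- call_roh(g, lmap, model)
    summ <- roh_summary(tracts, chrom_lengths_or_max(g))
    outs <- c(tsv(tracts, "roh_tracts.tsv"),
              tsv(summ$per_line, "roh_per_line.tsv"))
    done("roh", unclass(model), outs)
  }

  # --- structural variants ----------------------------------------------
  if ("svmerge" %in% stages && !is.null(config$sv_records)) {
    recs <- read.table(config$sv_records, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    svp <- config$sv %||% list()
    res <- sv_pipeline(recs, lmap,
                       breakpoint_tol = svp$breakpoint_tol %||% 1000,
                       min_callers = svp$min_callers %||% 2,
                       min_samples = svp$min_samples %||% 10)
    outs <- c(tsv(res$classified, "sv_classified.tsv"),
              tsv(res$summary, "sv_summary.tsv"))
    done("svmerge", svp, outs)
  }

  all_outputs <- unlist(lapply(manifest$stages, function(s) s$outputs))
  manifest$checksums <- as.list(tools::md5sum(all_outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
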