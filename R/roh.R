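#' Two-state runs-of-homozygosity HMM model parameters
#'
#' The chain has a Hardy-Weinberg (outbred) state and an autozygous state.
#' Emissions combine the per-site genotype likelihoods with either
#' Hardy-Weinberg genotype priors at the site's allele frequency or the
#' autozygous prior (homozygote probabilities 1-p and p with a residual
#' heterozygosity rate `eps`). Transitions depend on the genetic distance
#' between adjacent sites: P(switch) = 1 - exp(-t * d_cM).
#'
#' @param az_het_rate residual heterozygosity within autozygous tracts
#'   (default 1e-3).
#' @param t_hw_az switch rate HW -> AZ per cM (default 1e-2).
#' @param t_az_hw switch rate AZ -> HW per cM (default 5e-2).
#' @param rec_rate_cM_per_Mb constant recombination rate (default 0.51).
#' @return A `roh_model` list.
#' @export
roh_model <- function(az_het_rate = 1e-3, t_hw_az = 1e-2, t_az_hw = 5e-2,
                      rec_rate_cM_per_Mb = 0.51) {
  stopifnot(az_het_rate > 0, az_het_rate < 0.5,
            t_hw_az > 0, t_hw_az < 1, t_az_hw > 0, t_az_hw < 1)
  structure(list(az_het_rate = az_het_rate, t_hw_az = t_hw_az,
                 t_az_hw = t_az_hw, rec_rate_cM_per_Mb = rec_rate_cM_per_Mb),
            class = "roh_model")
}

#' Per-state emission probabilities from genotype likelihoods
#'
#' Genotype likelihoods are recovered from the phred-scaled PL triple
#' (L(g) = 10^(-PL_g/10), normalized to sum 1). The HW emission is
#' sum_g HWE(g; p) L(g); the autozygous emission is
#' (1-eps)((1-p) L(RR) + p L(AA)) + eps L(RA).
#'
#' @param pl matrix or data.frame with columns RR, RA, AA of phred-scaled
#'   likelihoods (rows = sites).
#' @param p alt allele frequency per site.
#' @param eps residual heterozygosity rate of the autozygous state.
#' @return matrix with columns `hw` and `az`.
#' @export
emission_probs <- function(pl, p, eps = 1e-3) {
  pl <- as.matrix(pl)
  lik <- 10^(-pl / 10)
  lik <- lik / rowSums(lik)
  hw <- (1 - p)^2 * lik[, 1] + 2 * p * (1 - p) * lik[, 2] + p^2 * lik[, 3]
  az <- (1 - eps) * ((1 - p) * lik[, 1] + p * lik[, 3]) + eps * lik[, 2]
  cbind(hw = hw, az = az)
}

#' Call runs of homozygosity per sample with the two-state HMM
#'
#' For each sample and chromosome, usable sites (PL present, allele frequency
#' defined) are decoded by Viterbi with distance-dependent transition
#' probabilities; maximal runs of the autozygous state become tracts whose
#' coordinates span the first to last autozygous site. The mean
#' forward-backward posterior of the autozygous state over the tract's sites
#' is reported as a quality measure. Allele frequencies default to the
#' global (all-sample) frequencies of the call set, mirroring the use of a
#' joint multi-sample VCF; per-line frequencies are available as an option,
#' but within a deeply drifted line autozygosity across line-fixed regions
#' is undetectable against the line's own frequencies.
#'
#' @param g a `genotype_data` with `pl` matrices.
#' @param lm a `line_map`.
#' @param model a [roh_model()].
#' @param samples samples to decode (default all).
#' @param af_scope `"global"` (default) or `"line"` allele frequencies.
#' @return data.frame: sample, line, chrom, start, end, length, n_sites,
#'   mean_posterior.
#' @export
call_roh <- function(g, lm, model = roh_model(), samples = g$samples,
                     af_scope = c("global", "line")) {
  af_scope <- match.arg(af_scope)
  if (is.null(g$pl)) stop("genotype likelihoods (PL) are required for RoH calling")
  af <- line_allele_frequencies(g, lm, include_pseudo = FALSE)
  called <- rowSums(!is.na(g$gt))
  p_glob <- ifelse(called > 0, rowSums(g$gt, na.rm = TRUE) / (2 * called), NA)
  init_az <- model$t_hw_az / (model$t_hw_az + model$t_az_hw)
  out <- list()
  for (smp in samples) {
    sc <- match(smp, g$samples)
    ln <- unname(lm$assignment[smp])
    p_site <- if (af_scope == "line") af$p[, ln] else p_glob
    pl_s <- cbind(g$pl$RR[, sc], g$pl$RA[, sc], g$pl$AA[, sc])
    usable <- !is.na(p_site) & rowSums(is.na(pl_s)) == 0 &
      (if (!is.null(g$dp)) g$dp[, sc] > 0 else TRUE)
    for (ch in unique(g$sites$chrom)) {
      idx <- which(usable & g$sites$chrom == ch)
      if (length(idx) < 2) next
      em <- emission_probs(pl_s[idx, , drop = FALSE], p_site[idx],
                           eps = model$az_het_rate)
      logem <- log(pmax(em, 1e-300))
      d_cm <- diff(g$sites$pos[idx]) * model$rec_rate_cM_per_Mb / 1e6
      p01 <- 1 - exp(-model$t_hw_az * d_cm)
      p10 <- 1 - exp(-model$t_az_hw * d_cm)
      path <- cpp_viterbi2(logem, p01, p10, 1 - init_az, init_az)
      if (!any(path == 1L)) next
      post <- cpp_posterior2(logem, p01, p10, 1 - init_az, init_az)
      r <- rle(path == 1L)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      w <- which(r$values)
      out[[length(out) + 1L]] <- data.frame(
        sample = smp, line = ln, chrom = ch,
        start = g$sites$pos[idx[starts[w]]],
        end = g$sites$pos[idx[ends[w]]],
        n_sites = r$lengths[w],
        mean_posterior = vapply(w, function(k)
          mean(post[starts[k]:ends[k]]), 0))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), line = character(), chrom = character(),
               start = integer(), end = integer(), n_sites = integer(),
               mean_posterior = numeric())
  res$length <- res$end - res$start
  rownames(res) <- NULL
  res[, c("sample", "line", "chrom", "start", "end", "length", "n_sites",
          "mean_posterior")]
}

#' Genome fraction in runs of homozygosity, by tract length class
#'
#' @param tracts output of [call_roh()] (or a compatible data.frame with
#'   sample, line, length columns).
#' @param chrom_lengths named chromosome lengths; their sum is the genome
#'   length.
#' @param classes list of `c(lower, upper)` length bounds in bp; a tract is
#'   counted in the class with lower < length <= upper. Defaults to
#'   (0, 1 Mb], (1, 8 Mb], (8 Mb, Inf).
#' @return list: `per_sample` (data.frame sample, line, class columns and
#'   total fraction), `per_line` (mean and sd of the fractions across the
#'   line's samples).
#' @export
roh_summary <- function(tracts, chrom_lengths,
                        classes = list(c(0, 1e6), c(1e6, 8e6), c(8e6, Inf))) {
  genome <- sum(chrom_lengths)
  cls_name <- vapply(classes, function(cl)
    sprintf("len_%s_%s", format(cl[1], scientific = FALSE),
            ifelse(is.finite(cl[2]), format(cl[2], scientific = FALSE), "Inf")), "")
  samples <- unique(tracts[, c("sample", "line")])
  per_sample <- samples
  for (k in seq_along(classes)) per_sample[[cls_name[k]]] <- 0
  per_sample$total <- 0
  for (i in seq_len(nrow(samples))) {
    tt <- tracts[tracts$sample == samples$sample[i], ]
    for (k in seq_along(classes)) {
      sel <- tt$length > classes[[k]][1] & tt$length <= classes[[k]][2]
      per_sample[[cls_name[k]]][i] <- sum(tt$length[sel]) / genome
    }
    per_sample$total[i] <- sum(tt$length) / genome
  }
  agg <- function(f) {
    do.call(rbind, lapply(split(per_sample, per_sample$line), function(d) {
      v <- vapply(c(cls_name, "total"), function(cn) f(d[[cn]]), 0)
      as.data.frame(c(list(line = d$line[1]), as.list(v)))
    }))
  }
  per_line_mean <- agg(mean)
  per_line_sd <- agg(function(x) if (length(x) > 1) sd(x) else 0)
  rownames(per_line_mean) <- rownames(per_line_sd) <- NULL
  list(per_sample = per_sample, per_line = per_line_mean,
       per_line_sd = per_line_sd, classes = classes)
}
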