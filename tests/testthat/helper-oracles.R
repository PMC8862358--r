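# Independent brute-force oracles used to cross-check the implementation.
# These are written from the definitions, not by calling package internals.

# Weir & Cockerham (1984) variance components for r populations, written in
# the general summation form (scalar, one site).
wc_oracle <- function(j, n, h) {
  r <- length(n)
  p <- j / (2 * n)
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       fst = if ((a + b + cc) == 0) NA_real_ else a / (a + b + cc))
}

# random draw of a valid two-population count configuration
random_wc_config <- function() {
  n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
  j1 <- sample(0:(2 * n1), 1); j2 <- sample(0:(2 * n2), 1)
  # heterozygote count consistent with the alt count
  h1 <- sample(0:min(j1, 2 * n1 - j1), 1) / n1
  h2 <- sample(0:min(j2, 2 * n2 - j2), 1) / n2
  list(j1 = j1, n1 = n1, h1 = h1, j2 = j2, n2 = n2, h2 = h2)
}

# quadratic interval-overlap oracle; site footprint [pos, pos+len) (1-based
# pos), intervals 0-based half-open (start, end)
overlap_oracle <- function(pos, len, starts, ends) {
  vapply(seq_along(pos), function(i) {
    a <- pos[i]; b <- pos[i] + max(len[i], 1L)  # exclusive
    any(a < ends + 1L & b > starts + 1L)
  }, TRUE)
}

# connected components of SV records linked when same type/chrom and both
# breakpoints within tol (BFS, quadratic)
sv_cluster_oracle <- function(recs, tol) {
  n <- nrow(recs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    adj[i, k] <- recs$svtype[i] == recs$svtype[k] &&
      recs$chrom[i] == recs$chrom[k] &&
      abs(recs$start[i] - recs$start[k]) <= tol &&
      abs(recs$end[i] - recs$end[k]) <= tol
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# brute-force SV caller-filter predicates (one logical per record)
sv_filter_oracle <- function(r) {
  keep <- logical(nrow(r))
  for (i in seq_len(nrow(r))) {
    keep[i] <- switch(r$caller[i],
      manta = r$mapq[i] >= 30 && r$depth_ratio[i] <= 3 &&
        r$gq[i] >= 20 && r$depth[i] >= 5,
      whamg = r$length[i] >= 50 && r$length[i] <= 2e6 &&
        r$depth[i] >= 5 && r$gq[i] >= 20 && r$cross_chrom_fraction[i] <= 0.1,
      lumpy = r$su[i] >= 5 && r$gq[i] >= 20)
  }
  keep
}

# exhaustive-path scoring for a 2-state HMM chain (log space)
viterbi_oracle <- function(logem, p01, p10, init0, init1) {
  n <- nrow(logem)
  paths <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  score <- apply(paths, 1, function(st) {
    s <- log(c(init0, init1)[st[1] + 1]) + logem[1, st[1] + 1]
    for (i in seq_len(n - 1)) {
      tr <- if (st[i] == 0) {
        if (st[i + 1] == 0) log(1 - p01[i]) else log(p01[i])
      } else {
        if (st[i + 1] == 1) log(1 - p10[i]) else log(p10[i])
      }
      s <- s + tr + logem[i + 1, st[i + 1] + 1]
    }
    s
  })
  list(path = paths[which.max(score), ], score = score, paths = paths)
}
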