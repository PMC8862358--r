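#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Gamete formation for a batch of offspring.
//
// haps / anc: n_sites x (2*n_ind) raw matrices of haploid alleles (0/1) and
// founder-haplotype ancestry labels; columns 2i, 2i+1 are the two haplotypes
// of individual i (sites x haplotypes keeps segment copies contiguous in
// memory). Sites are sorted by chromosome then position; chrom_start gives
// the 0-based first site index of each chromosome (length n_chrom + 1, last
// element = n_sites). morgan holds the genetic-map position of each site in
// Morgans; chrom_len_morgan is the total map length per chromosome.
//
// For each requested gamete (parent index, 0-based individual), the number
// of crossovers per chromosome is Poisson(map length) with positions uniform
// on the map. linked = false draws an independent fair coin per site (free
// recombination, used for unlinked-sites experiments).
//
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_make_gametes(RawMatrix haps, RawMatrix anc, IntegerVector parents,
                      IntegerVector chrom_start, NumericVector morgan,
                      NumericVector chrom_len_morgan, bool linked,
                      bool track_anc) {
  const int n_sites = haps.nrow();
  const int n_gam = parents.size();
  const int n_chrom = chrom_len_morgan.size();
  RawMatrix out(n_sites, n_gam);
  RawMatrix out_anc(track_anc ? n_sites : 1, track_anc ? n_gam : 1);
  const Rbyte* hp = haps.begin();
  const Rbyte* ap = anc.begin();
  Rbyte* op = out.begin();
  Rbyte* oap = out_anc.begin();
  std::vector<double> bp;

  for (int g = 0; g < n_gam; ++g) {
    const int pa = parents[g];
    const Rbyte* colA = hp + (size_t)(2 * pa) * n_sites;
    const Rbyte* colB = colA + n_sites;
    const Rbyte* ancA = ap + (size_t)(2 * pa) * n_sites;
    const Rbyte* ancB = ancA + n_sites;
    Rbyte* dst = op + (size_t)g * n_sites;
    Rbyte* dsta = oap + (size_t)g * n_sites;
    if (!linked) {
      for (int s = 0; s < n_sites; ++s) {
        const bool b = unif_rand() < 0.5;
        dst[s] = b ? colB[s] : colA[s];
        if (track_anc) dsta[s] = b ? ancB[s] : ancA[s];
      }
      continue;
    }
    for (int c = 0; c < n_chrom; ++c) {
      const int s0 = chrom_start[c], s1 = chrom_start[c + 1];
      int phase = (unif_rand() < 0.5) ? 1 : 0;
      const int k = (int) R::rpois(chrom_len_morgan[c]);
      int seg = s0;
      if (k > 0) {
        bp.resize(k);
        for (int i = 0; i < k; ++i) bp[i] = unif_rand() * chrom_len_morgan[c];
        std::sort(bp.begin(), bp.end());
        for (int i = 0; i < k; ++i) {
          // first site strictly beyond this crossover
          const double x = bp[i];
          int lo = seg, hi = s1;
          while (lo < hi) {
            const int mid = (lo + hi) / 2;
            if (morgan[mid] <= x) lo = mid + 1; else hi = mid;
          }
          if (lo > seg) {
            const Rbyte* src = phase ? colB : colA;
            std::memcpy(dst + seg, src + seg, lo - seg);
            if (track_anc) {
              const Rbyte* srca = phase ? ancB : ancA;
              std::memcpy(dsta + seg, srca + seg, lo - seg);
            }
            seg = lo;
          }
          phase ^= 1;
        }
      }
      if (s1 > seg) {
        const Rbyte* src = phase ? colB : colA;
        std::memcpy(dst + seg, src + seg, s1 - seg);
        if (track_anc) {
          const Rbyte* srca = phase ? ancB : ancA;
          std::memcpy(dsta + seg, srca + seg, s1 - seg);
        }
      }
    }
  }
  return List::create(_["haps"] = out, _["anc"] = out_anc);
}

// Dosage (0/1/2) of selected individuals: haps is sites x (2*n_ind) raw;
// cols holds 0-based individual indices. Returns sites x length(cols).
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(RawMatrix haps, IntegerVector cols) {
  const int n_sites = haps.nrow();
  const int n = cols.size();
  IntegerMatrix out(n_sites, n);
  const Rbyte* hp = haps.begin();
  for (int i = 0; i < n; ++i) {
    const Rbyte* a = hp + (size_t)(2 * cols[i]) * n_sites;
    const Rbyte* b = a + n_sites;
    int* o = out.begin() + (size_t)i * n_sites;
    for (int s = 0; s < n_sites; ++s) o[s] = (int)a[s] + (int)b[s];
  }
  return out;
}

// Column subset of a raw matrix (0-based indices), used to gather the
// haplotype columns of selected individuals without R-level copies.
// [[Rcpp::export]]
RawMatrix cpp_subset_cols(RawMatrix m, IntegerVector cols) {
  const int nr = m.nrow();
  RawMatrix out(nr, cols.size());
  for (int i = 0; i < cols.size(); ++i) {
    std::memcpy(out.begin() + (size_t)i * nr,
                m.begin() + (size_t)cols[i] * nr, nr);
  }
  return out;
}

// Viterbi decoding of a two-state HMM (state 0 = non-autozygous, 1 =
// autozygous) with site-specific log emissions (n x 2) and interval-specific
// switch probabilities p01[i], p10[i] between site i and i+1.
// [[Rcpp::export]]
IntegerVector cpp_viterbi2(NumericMatrix logem, NumericVector p01,
                           NumericVector p10, double init0, double init1) {
  const int n = logem.nrow();
  IntegerVector path(n);
  if (n == 0) return path;
  std::vector<signed char> bt0(n, 0), bt1(n, 0);
  double v0 = std::log(init0) + logem(0, 0);
  double v1 = std::log(init1) + logem(0, 1);
  for (int i = 1; i < n; ++i) {
    const double l00 = std::log1p(-p01[i - 1]), l01 = std::log(p01[i - 1]);
    const double l11 = std::log1p(-p10[i - 1]), l10 = std::log(p10[i - 1]);
    const double a0 = v0 + l00, b0 = v1 + l10;
    const double a1 = v0 + l01, b1 = v1 + l11;
    double n0, n1;
    if (a0 >= b0) { n0 = a0; bt0[i] = 0; } else { n0 = b0; bt0[i] = 1; }
    if (a1 >= b1) { n1 = a1; bt1[i] = 0; } else { n1 = b1; bt1[i] = 1; }
    v0 = n0 + logem(i, 0);
    v1 = n1 + logem(i, 1);
  }
  int st = (v1 > v0) ? 1 : 0;
  path[n - 1] = st;
  for (int i = n - 1; i > 0; --i) {
    st = st ? bt1[i] : bt0[i];
    path[i - 1] = st;
  }
  return path;
}

// Scaled forward-backward for the same two-state chain; returns the
// posterior probability of the autozygous state at each site.
// [[Rcpp::export]]
NumericVector cpp_posterior2(NumericMatrix logem, NumericVector p01,
                             NumericVector p10, double init0, double init1) {
  const int n = logem.nrow();
  NumericVector post(n);
  if (n == 0) return post;
  std::vector<double> f0(n), f1(n);
  double m = std::max(logem(0, 0), logem(0, 1));
  f0[0] = init0 * std::exp(logem(0, 0) - m);
  f1[0] = init1 * std::exp(logem(0, 1) - m);
  double sc = f0[0] + f1[0]; f0[0] /= sc; f1[0] /= sc;
  for (int i = 1; i < n; ++i) {
    m = std::max(logem(i, 0), logem(i, 1));
    const double e0 = std::exp(logem(i, 0) - m), e1 = std::exp(logem(i, 1) - m);
    const double t00 = 1.0 - p01[i - 1], t01 = p01[i - 1];
    const double t11 = 1.0 - p10[i - 1], t10 = p10[i - 1];
    f0[i] = (f0[i - 1] * t00 + f1[i - 1] * t10) * e0;
    f1[i] = (f0[i - 1] * t01 + f1[i - 1] * t11) * e1;
    sc = f0[i] + f1[i]; f0[i] /= sc; f1[i] /= sc;
  }
  double b0 = 1.0, b1 = 1.0;
  post[n - 1] = f1[n - 1] / (f0[n - 1] + f1[n - 1]);
  for (int i = n - 2; i >= 0; --i) {
    m = std::max(logem(i + 1, 0), logem(i + 1, 1));
    const double e0 = std::exp(logem(i + 1, 0) - m), e1 = std::exp(logem(i + 1, 1) - m);
    const double t00 = 1.0 - p01[i], t01 = p01[i];
    const double t11 = 1.0 - p10[i], t10 = p10[i];
    const double nb0 = t00 * e0 * b0 + t01 * e1 * b1;
    const double nb1 = t10 * e0 * b0 + t11 * e1 * b1;
    sc = nb0 + nb1;
    b0 = nb0 / sc; b1 = nb1 / sc;
    const double g0 = f0[i] * b0, g1 = f1[i] * b1;
    post[i] = g1 / (g0 + g1);
  }
  return post;
}
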