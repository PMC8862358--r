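---
title: "Population-genomic analysis of long-term selection lines: models and methods"
author: "lineselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic analysis of long-term selection lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

`lineselect` analyses whole-genome variant data from multi-line selective
breeding experiments: several lines bred from one admixed founder population,
each under long-term truncation selection for a different trait, alongside an
unselected control maintained at larger census size. After one to two hundred
generations at effective sizes of a few hundred, plus a relocation bottleneck
that refounded each line from a handful of breeding pairs, such genomes are
dominated by drift: most variants are fixed within lines, linkage
disequilibrium extends over megabases, and much of each genome lies in long
runs of homozygosity. The analytical challenge is to quantify this structure
(diversity, differentiation, homozygosity, LD) and to isolate the rare
regions where one line's differentiation from the control is *specific* to
that line rather than a generic product of drift.

The package implements the full desk-side pipeline — variant filtering,
per-line allele-frequency accounting, Weir–Cockerham F~ST~ window scans with
detection of regions of distinct genetic differentiation (RDDs), LD decay,
a genotype-likelihood HMM for runs of homozygosity, and consensus filtering
of multi-caller structural-variant records — together with a forward-in-time
simulator of the breeding design that provides a fully synthetic,
ground-truthed test substrate, so that every stage is validated without any
external data.

# Input filtering

Genotype calls are marked missing when read depth is below 4, above the
sample's mean depth plus three standard deviations, or when genotype quality
is below 20 (`apply_genotype_filters()`). The per-sample depth summaries are
computed over the cells with *recorded* depth, which filtering never erases;
this makes the filter idempotent and independent of which genotypes were
previously masked. Sites are then retained only if every line has a
non-missing call in at least 15 samples, with a per-line override (12) for a
line sequenced at lower coverage (`site_support_filter()`). "Present in a
line" is read as "has a genotype call", not "carries the alternative
allele": lines fixed for the reference allele at a site are real
observations that the downstream classification (fixed/polymorphic) needs.
An `require_alt` switch implements the stricter reading for users who want
it. INDELs overlapping a microsatellite track are removed by interval
subtraction on the half-open footprint `[pos, pos + L)`
(`exclude_intervals()`); coordinates are 1-based inclusive in VCF space and
converted once at the boundary.

# The breeding-design simulator

`sim_config()` describes the study design; its defaults encode the
experiment the package targets:

* an admixed founder pool produced by crossing four outbred strains
  (independent haplotypes) and four fully inbred strains (one haplotype per
  strain carried homozygously), eight founders each;
* six lines: one unselected control of 200 breeding pairs and five
  trait-selected lines of 60–100 pairs with per-line selected proportions
  between 0.5 and 0.7 (the historical ranges 25–80 % are collapsed to
  constant midpoints; the per-generation schedule varied historically, which
  the simulator deliberately does not reproduce);
* truncation selection on a polygenic trait: 100 QTL drawn from segregating
  founder sites, Normal effects, environmental noise calibrated so the trait
  has the configured heritability (default 0.3) in the founder pool;
* monogamous pairs with balanced litters, sized automatically so the next
  generation can be filled after selection; a `mating = "random"`
  Wright–Fisher mode (random union of gametes, selfing allowed) exists for
  calibration experiments where exact drift expectations are needed;
* a relocation bottleneck at generation 160 refounding each line from
  7–55 random pairs, and sampling of 25 individuals per line at
  generation 188;
* recombination at a constant 0.51 cM/Mb (the mouse genome average) with
  Poisson crossovers; no new mutation — standing founder variation only,
  consistent with the observation that the overwhelming majority of
  selected-line variants segregate in the control;
* a sequencing emulator producing per-cell read depths (Poisson), allele
  counts (Binomial with base error 10^-3^), phred-scaled genotype
  likelihoods, GQ and calls at two coverage regimes, 24× for 10 samples and
  8× for 15 samples per line, mirroring a 30×/5× sequencing design's
  realized coverages.

The genome is desk-scale — three 20-Mb autosomes with 24,000 candidate sites
(about one segregating site per 3 kb, so 50-kb windows hold well over the
10-SNP minimum) — while all population-genetic parameters stay at study
scale. Validation shows this reproduces the study regime quantitatively: the
default design yields genome-wide window-mean F~ST~ of ≈0.27–0.33 between
selected lines and the control and ≈0.43–0.55 among selected lines, with the
least-bottlenecked line least differentiated.

Founder-haplotype ancestry labels are carried through every meiosis, so each
sampled individual's true autozygous tracts (runs where both haplotypes
descend from the same founder haplotype) are known exactly; these, the QTL
list, per-generation QTL frequency trajectories, and the retained-parent
pedigree form the simulator's ground truth. What the simulator does *not*
emulate: new mutations, the X chromosome (windows from real data on X are
handled by the scan's separate standardization instead), overlapping
generations and litter-size variation, reference-alignment artifacts, and
base-quality structure beyond a uniform error rate. Tests passing on this
substrate therefore validate the statistical machinery, not robustness to
alignment or calling artifacts.

# Differentiation scan

Per-site F~ST~ uses the Weir–Cockerham (1984) two-population
variance-component estimator, computed from allele counts, diploid sample
sizes and observed heterozygote frequencies; sites where both populations
are monomorphic for the same configuration (zero total variance) are
undefined and excluded. Windows of 50 kb tiled every 25 kb from position 1
carry the *arithmetic mean* of the per-SNP values (negative estimates
included as-is); windows with fewer than 10 defined SNPs are suppressed.
Window means are z-standardized against the genome-wide window distribution
with the X chromosome standardized separately (population-divisor standard
deviation), since its effective population size differs.

Genome-wide pairwise values (`genomewide_mean_fst()`) default to the mean of
window means, consistent with the windowed scan; the multi-locus
ratio-of-sums estimator (sum of `a` components over sum of `a+b+c`) is
available as an option and is the estimator used by the drift-validation
experiment, because the mean of per-site ratios is biased at small sample
sizes whereas the ratio of summed components is (nearly) unbiased — under
neutral two-population drift it recovers the analytic expectation
1 − (1 − 1/2N)^t^ within Monte-Carlo error.

RDDs are windows simultaneously at or above the target contrast's 95th
percentile and at or below the 10th percentile of *every* other contrast,
merged across overlapping/abutting windows. Percentiles use linear
interpolation between order statistics (R's default type 7); boundary
comparisons are inclusive on both sides. Two under-specified corners are
resolved conservatively: a window absent (min-SNP-failing) from any other
contrast is disqualified rather than vacuously passing, and contrasts that
share samples with the target — the pooled fertility pseudo-line versus its
member lines — are excluded from the "all other contrasts" rule, since a
window cannot plausibly be extreme in a pooled contrast and null in its
members simultaneously.

A point worth stating openly, because the package's own validation
experiment (`rdd_sweep_experiment()`) measures it: under the default
breeding design a *single-locus sweep in the target line does not reliably
produce an RDD*. After 188 generations at these effective sizes plus the
bottleneck, drift alone pushes many windows to F~ST~ ≈ 1, so a swept window
does not stand out in the target contrast; and the joint requirement of
sitting in the bottom decile of four to five independently drifted contrasts
has empirical probability near zero at desk-scale window counts (a
50-times-larger real genome offers proportionally more chances). The RDD
rule is a high-specificity instrument — the fully neutral design produces
essentially no RDDs (`rdd_neutral_experiment()`), and thresholds behave
monotonically — not a high-sensitivity sweep detector, which matches its
role in the source experiment, where thresholds were tuned empirically
precisely because outstanding outlier regions were absent.

# Nucleotide diversity

Per SNP site, π is the mean pairwise difference among called chromosomes,
2j(n−j)/(n(n−1)) — the unbiased estimator on the realized sample — summed
over the window and divided by the window length in bp. Windows are
position-tiled like the F~ST~ windows. No minimum SNP count is imposed
(windows report their SNP count so users can filter); a site needs at least
two called chromosomes.

# Linkage disequilibrium

Sites are greedily thinned left-to-right to a 100-kb minimum spacing per
chromosome; r² is the squared Pearson correlation of alt-dosage vectors over
pairwise-complete samples for same-chromosome pairs up to 5 Mb (composite,
genotype-based r² — phase is not available and not assumed). Pairs with
fewer than two complete samples or zero variance at either site are skipped;
no MAF filter is applied by default (flag available). Decay curves bin pairs
into 0.1-Mb classes from 0.1 to 5 Mb, reporting per-bin means and counts
(empty bins kept with count 0). The LD validation experiment uses a larger,
sparser genome (six 40-Mb chromosomes, ~2,400 thinned sites) because
100-kb-thinned pairs, not SNP density, are what the statistic consumes.

# Runs of homozygosity

The caller is a two-state HMM on genotype likelihoods — the inputs the
source pipeline fed to its external caller (per-site allele frequencies, a
constant 0.51 cM/Mb map, PL triples) — with the internals fixed by this
package since the original tool's are not part of the data contract:

* emissions: Hardy–Weinberg state, Σ~g~ HWE(g; p)·L(g); autozygous state,
  (1−ε)((1−p)L(RR) + pL(AA)) + εL(RA) with residual heterozygosity
  ε = 10^-3^; L(g) = 10^(−PL~g~/10)^ normalized (decoding is invariant to
  uniform PL shifts);
* transitions between adjacent usable sites: P(switch) = 1 − exp(−t·d~cM~),
  with t = 10^-2^ per cM into and 5×10^-2^ per cM out of the autozygous
  state; the stationary distribution initializes each chromosome;
* Viterbi decoding defines tracts (first to last autozygous site); the
  forward–backward posterior over the tract is reported as a quality score.

Allele frequencies default to the *global* all-sample frequencies of the
call set, as carried by a joint multi-sample VCF. This matters: against a
deeply drifted line's own frequencies, line-fixed regions are monomorphic
and hence invisible to any frequency-based emission model, and measured
recall of true ≥1-Mb autozygous tracts drops from ~1.0 to ~0.74. Per-line
frequencies remain available (`af_scope = "line"`). Genome fractions are
summarized by tract-length class, default (0,1], (1,8], (8,∞) Mb; only the
1 and 8 Mb edges are meaningful defaults, the rest is configuration.

# Structural-variant consensus

The SV module post-processes per-sample records from three callers (the
callers themselves are out of scope): caller-specific filters (manta:
MAPQ ≥ 30, coverage ≤ 3× the chromosome median, GQ ≥ 20, depth ≥ 5×; whamg:
50 bp–2 Mb, depth ≥ 5×, GQ ≥ 20, low cross-chromosomal mapping; lumpy:
SU ≥ 5, GQ ≥ 20), then per line and coverage set a transitive breakpoint
clustering (same type and chromosome, both breakpoints within 1,000 bp — a
common merge distance, configurable) requiring at least two distinct
callers, median consensus coordinates, a ≥10-distinct-sample support filter
counted *after* merging (switchable), the union of the high- and
low-coverage sets with tolerance-matched deduplication, removal of SVs in
assembly gaps or excessive-coverage regions, and classification:
line-specific (no tolerance match in any other line), fixed (every genotyped
sample of the line is a homozygous carrier — the package's own operational
definition, since none is inherited from the data), and genic (any-overlap
with gene intervals). Insertions are parsed but excluded from consensus
output by default; they rarely reach sample-support thresholds. The summary
table mirrors the per-line total and line-specific-genic counts by type.

# Validation experiments and problem sizes

`R/validate.R` packages the experiments that the test suite and the
acceptance script run; all sizes are package choices made once:

* `drift_experiment()` — 20 replicates, two populations of 25 pairs
  (2N = 100), 50 generations, 2,000 unlinked sites, Wright–Fisher mating;
  multi-locus F~ST~ versus 1 − (1 − 1/100)^50^.
* `rdd_sweep_experiment()` — 10 replicates of the default six-line design
  with a single large-effect QTL (heritability 0.5, founder MAF ≥ 0.2)
  selected in the target line only.
* `rdd_neutral_experiment()` — 5 replicates, selection disabled everywhere;
  qualifying-window counts versus the independence chance expectation
  (binomial test) and QTL-position enrichment.
* `roh_experiment()` — 8 replicates of control + two bottlenecked selected
  lines, sequencing emulated, RoH called on the 24× samples; pooled recall
  of true ≥1-Mb autozygous bases and the per-replicate line ordering.
* `ld_experiment()` — one replicate, control + most-bottlenecked line on the
  sparser LD genome.

# Known limitations

The simulator's drift, bottleneck and selection machinery is validated
against analytic and ground-truth oracles, but the synthetic data are
cleaner than real resequencing data: no calling artifacts, no reference
bias, no mutation. The RDD sensitivity caveat above is the main scientific
limitation and is reported, not hidden, by the validation suite. The SV
module trusts its input records' support fields; it re-derives nothing from
reads. Hierarchical IBS clustering is quadratic in samples and intended for
cohort-scale (hundreds), not biobank-scale, data.
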