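Package: lineselect
Title: Population Genomics of Long-Term Selection Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-line selective-breeding experiments
    genotyped by whole-genome sequencing. Reads multi-sample VCFs, applies
    depth/quality genotype filters and per-line site-support rules, and computes
    per-line allele-frequency accounting (fixed/polymorphic/private/shared
    sites, allele-frequency spectra, windowed nucleotide diversity,
    identity-by-state clustering), Weir-Cockerham F_ST sliding-window scans
    with z-standardization and detection of regions of distinct genetic
    differentiation, linkage-disequilibrium decay curves, a genotype-likelihood
    hidden Markov model caller for runs of homozygosity, and consensus
    filtering of multi-caller structural-variant records. A forward-in-time
    Wright-Fisher simulator of a multi-line breeding design with truncation
    selection and relocation bottlenecks provides a fully synthetic test
    substrate with ground-truth QTL positions and autozygous tracts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
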