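Package: svpanel
Title: Genic Structural-Variant Discovery Across an Inbred Panel from
    Array-CGH and Resequencing Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dual-platform discovery of genic copy-number and
    presence-absence variation (CNV/PAV) across a panel of inbred lines
    compared with a single reference genotype. Implements array-CGH log2
    ratio segmentation and thresholding, read-depth (RPKM) ratio calling
    with zero-read special streams, cross-platform validation, six-category
    structural-variant classification with per-genotype copy estimates,
    collapsing of adjacent calls into segments, reference-ascertained site
    frequency spectra compared against a built-in neutral coalescent with
    recombination, hypergeometric domain-enrichment tests with
    resampling-based family-wise correction, and a paralog-retention
    contrast. A synthetic-data generator with planted truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
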