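Package: cagepeakr
Title: Two-Stage Peak Calling and TSS Classification for CAGE-seq Data
Version: 0.1.0
Authors@R:
    person("cagepeakr", "developers", email = "cagepeakr@example.org",
           role = c("aut", "cre"))
Description: Detects read-start peaks in cap-analysis gene expression (CAGE)
    sequencing data with a strand-specific sliding-window scan tested against
    local Poisson null distributions estimated from flanking windows, then
    classifies each peak as a transcription start site (TSS) peak or a
    non-TSS (e.g. recapping) peak with a class-weighted L2-regularised
    squared-hinge linear support vector machine. Includes promoter-sequence
    4-mer, peak-shape (kurtosis, read density), external-track
    (conservation, TFBS, DNase, H3K4me3) and RNA-seq flank-asymmetry feature
    extraction, principal-component based feature selection, leave-one-cell-
    line-out evaluation, and a seed-deterministic synthetic-data generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
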