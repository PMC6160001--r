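Package: clockbind
Title: Cistrome Co-Binding Proximity Analysis for Circadian
    Glucocorticoid Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying co-binding between two transcription
    factor cistromes from ChIP-seq summit proximity: nearest-summit
    distance distributions, the co-binding ratio (proximal versus
    non-proximal binding events at a distance threshold), fold-enrichment
    stringency filtering, cistrome pooling and overlap, and extraction of
    co-bound peak pairs. Downstream helpers map co-bound peaks to nearest
    transcription start sites, stratify condition-labelled differential
    expression gene sets by genotype and time of day, compute TSS-anchored
    metagene fold-change profiles from binned histone-acetylation
    coverage, rank known-motif enrichment by observed/expected ratio, and
    normalize ChIP-ddPCR copy numbers against a spike-in reference. A
    seeded synthetic-data generator with recorded ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
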