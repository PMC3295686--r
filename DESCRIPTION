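Package: mbdscan
Title: Peak Calling and Differential Methylation Analysis for Methylated-DNA Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for methyl-binding-protein capture sequencing
    (MBD/MBP-seq). Calls methylated regions per sample with a windowed scan
    against a negative-binomial background fitted on low-coverage windows,
    using an empirical false discovery rate defined as the ratio of the
    expected to the observed fraction of windows at a given read count.
    Candidate windows are merged and refined by the spatial separation of
    forward- and reverse-strand reads (one-sided Wilcoxon rank-sum test).
    Peaks are annotated to promoter, gene body, 3'-flanking and intergenic
    classes, classified as sample-specific hypo-/hypermethylation calls by
    cross-sample overlap, and peak-associated genes are tested for gene-set
    enrichment with a right-tailed Fisher's exact test. A synthetic-data
    module simulates methylation landscapes and capture-enriched read sets
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
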