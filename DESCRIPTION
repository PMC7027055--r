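Package: peakvar
Title: Cross-Cell-Line Variability Analysis of Transcription Factor
    Binding Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies transcription factor ChIP-seq signal over a
    consensus peak set across many cell lines, normalizes between
    samples, and separates Poisson counting ("shot") noise from genuine
    cross-cell-line variability with a mean-CV trend model to flag
    cell-line-specific binding sites. Also provides floor-adjusted
    position weight matrix scoring of peak sequences, variance
    decomposition of binding into motif and chromatin-accessibility
    components, correlation-distance average-linkage clustering,
    hypergeometric gene-set enrichment, and a synthetic multi-sample
    count simulator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    ape,
    mclust,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
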