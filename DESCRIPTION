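Package: cedseek
Title: Interactome Ranking, ChIP-Seq Peak Calling and Factorial
    Differential Expression for Bacterial Transcription Factor Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify a promoter-associated bacterial transcription
    factor from three complementary genome-scale assays. Implements
    combined-rank scoring of crosslink immunoprecipitation mass-spectrometry
    pulldowns (abundance, specificity and enrichment fractional ranks summed
    to a 0-1 score), a coverage-track ChIP-seq peak caller (log2 transform,
    50-bp rolling average, background and mode-baseline subtraction, 3-sigma
    local maxima), transcription start site association with -10 element
    position weight matrix construction, and a factorial-ANOVA differential
    expression stage with Benjamini-Hochberg correction and promoter
    cross-referencing. A synthetic-data module generates proteomics tables,
    coverage tracks, genome annotations and negative-binomial count matrices
    with planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
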