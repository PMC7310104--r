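Package: bisamp
Title: Targeted Multiplex Bisulphite Amplicon Sequencing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted DNA methylation panels assayed by multiplex
    bisulphite PCR sequencing: quality trimming and bisulphite-aware
    assignment of amplicon reads, per-CpG methylation calling, coverage
    quality control with primer rebalancing suggestions, PCR-bias
    calibration against methylated-control gradients, down-sampling
    sensitivity analysis, read-level epiallele pattern summaries, and a
    fully parameterised synthetic bisulphite read simulator for assay
    design and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
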