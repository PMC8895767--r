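Package: capcall
Title: Depth-Capped Resampling and Ensemble Variant Calling for Long-Read
    Target-Enrichment Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-variant calling on uneven-depth long-read
    target-enrichment (capture panel) sequencing data, such as nanopore
    medical-exome libraries. Implements by-position depth-capped read
    resampling with quality-preferential retention, ensemble averaging of
    per-partition genotype-task probabilities from pluggable probability
    models, variant decision logic producing VCF, capture coverage QC
    metrics (depth-of-coverage thresholds, uniformity, flanked splice-site
    coverage, uncovered-region detection with GC annotation, read length
    and quality statistics), precision/recall/F1 benchmarking against a
    truth set, and a synthetic capture-data simulator with planted
    variants and per-region capture bias for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
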