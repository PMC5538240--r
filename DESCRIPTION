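Package: oceanqc
Title: Quality Control and Filtering for Paired-End Marine Meta-Omics Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native reimplementation of the read preprocessing and
    dataset validation pipeline used for large-scale ocean metagenomic,
    metatranscriptomic and amplicon sequencing surveys. Provides adapter and
    quality trimming with longest-clean-segment selection, canonical k-mer
    screening for control-genome contaminants and for partitioning ribosomal
    reads, duplicate-rate estimation on random subsamples, seed-and-verify
    merging of overlapping read pairs with quality-aware consensus, per-dataset
    quality metrics, and a rule-based pass/warn/fail verdict. A deterministic
    paired-read simulator with insert-size, error, adapter read-through and
    spike-in models makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
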