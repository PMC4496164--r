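Package: chipcin
Title: ChIP-Seq Interval Enrichment and Chromosomal Instability Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tidy analysis pipeline for studying the genomic occupancy of a
    chromatin-associated regulator and its downstream chromosomal-instability
    (CIN) program. Provides ChIP-Seq tag extension, fragment-density binning
    and peak-to-gene annotation geometry; a genome-shuffling permutation
    framework for transcription-factor binding-site and interval-overlap
    enrichment with an exact-null-checkable placement model; a truncated
    Gaussian-KDE test for differential transcription-factor counts;
    differential-expression filtering and CIN-signature enrichment curves with
    matched-pairs comparison; karyotype aneuploidy classification and
    association tests; Kaplan-Meier/log-rank tumor-free survival comparison;
    and seeded synthetic-data generators that plant recoverable structure in
    every input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    survival,
    withr,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
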