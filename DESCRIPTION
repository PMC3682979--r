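Package: devotf
Title: Comparative Analysis of Transcription Factor Expression Across
    Embryogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing transcription-factor (TF) expression
    across developmental time courses of different species: presence/absence
    calling from detection flags or FPKM, TF-family utilization profiles,
    soft temporal clustering of expression profiles by fuzzy c-means,
    cross-species pairing of expression clusters, ortholog
    expression-conservation statistics against permutation nulls,
    per-time-point transcriptome distance ("hourglass") analysis, and
    ontology enrichment over a DAG with hierarchy decorrelation. Includes a
    two-species synthetic data generator with known ground truth so every
    stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    e1071,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
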