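Package: orthoclade
Title: Lineage-Specific Ortholog Group Classification and Comparative
    Gene-Set Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies core lineage-specific (e.g. metazoan-specific)
    ortholog groups from ortholog-clustering output using configurable
    per-clade presence thresholds and reciprocal-best-BLAST-hit (RBBH)
    leakage filtering, approximates genome completeness as coverage of a
    reference set of conserved low-copy eukaryotic genes, and runs the
    downstream comparative layer: hypergeometric category enrichment with
    Benjamini-Hochberg correction, RNAi phenotype-class comparisons,
    keyword-based expression-tissue classification, interaction-network
    partitioning, and disease/characterization flagging. A seeded
    synthetic-data generator plants ortholog worlds and annotation
    bundles with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
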