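Package: poolscreen
Title: Analysis and Simulation of Pooled shRNA Dropout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deconvolutes barcoded amplicon sequencing reads from pooled
    short-hairpin RNA (shRNA) dropout screens into count matrices, scores
    per-hairpin depletion against a pre-transplantation reference pool
    (library-size normalization, log2 fold change, robust z-scores), computes
    gene-level redundant shRNA activity (RSA) statistics with
    Benjamini-Hochberg false discovery rates, calls and intersects hits
    across screens, and reports screen quality-control metrics. Includes a
    synthetic screen generator that emulates an in vivo engraftment
    bottleneck so the whole pipeline can be exercised and validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
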