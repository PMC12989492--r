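Package: fluxdiff
Title: Expression-Constrained Metabolic Flux Simulation and Differential
    Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for contrasting metabolic states between two conditions
    from bulk RNA-seq. Per-sample transcript abundances (TPM) are mapped
    onto a genome-scale metabolic model through gene-protein-reaction
    rules, reaction flux bounds are scaled by normalized enzyme expression
    (an E-Flux-style constraint), and a two-stage linear program (maximal
    energy-pathway throughput, then parsimonious total flux) yields one
    comparable flux vector per sample. Per-reaction differences between
    groups are tested with the Van der Waerden normal-scores test with
    exact-permutation and normal-approximation modes and
    Benjamini-Hochberg correction. Companion tools cover TPM
    normalization, rank-based differential expression, consensus k-means
    clustering of fold-change profiles with consensus-matrix co-expression
    networks, offline protein-interaction network ingestion, hypergeometric
    over-representation analysis, a synthetic paired-cohort generator with
    planted enzyme effects and its gold-standard answer key, and a
    configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
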