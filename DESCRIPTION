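Package: multiclever
Title: Physico-Chemical and Gene Ontology Classification of Multiple Protein Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares multiple protein sequence datasets by physico-chemical
    propensity scales and by Gene Ontology annotation. Datasets are scored
    against a registry of amino-acid propensity scales organised into seven
    property groups (nucleic-acid binding, membrane, alpha-helix, aggregation,
    beta-sheet, burial, hydrophobicity); per-scale discrimination statistics
    (one-sided Fisher exact test, Mann-Whitney-Wilcoxon test, ROC/AUC,
    cross-validated threshold accuracy) are collated into a microarray-like
    consensus grid over all dataset pairs. A companion ontology toolkit
    performs GO term enrichment (hypergeometric test with Bonferroni
    correction, depth/precision filters) and clusters enriched terms by Lin
    semantic similarity with per-cluster protein coverage. Includes a
    synthetic-data generator for compositionally biased protein sets and toy
    ontologies, and a command-line interface for batch runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
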