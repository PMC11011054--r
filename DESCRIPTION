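Package: sctopics
Title: Topic Modeling of Single-Cell Multi-Omics with Hierarchical
    Stochastic Block Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters single cells and extracts interpretable gene
    signatures (topics) by fitting hierarchical, degree-corrected
    stochastic block models to weighted gene-cell networks. Supports
    multipartite fits that integrate several omics layers (e.g. mRNA and
    lncRNA counts) sharing the same cells, probabilistic topic and
    cluster extraction at every level of the inferred hierarchy, an
    adaptive topic-to-cluster assignment procedure, null-model-adjusted
    normalized mutual information scoring, and filtered hypergeometric
    gene-set enrichment of topics. Includes a synthetic-data generator
    with planted hierarchical structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    fgsea
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
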