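Package: fuzzyhep
Title: Constrained Fuzzy Logic Modelling of Cytokine-Driven Hepatic Gene Regulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for prior-knowledge-driven constrained fuzzy logic modelling of
    perturbation gene-expression data, motivated by the IL-6-induced downregulation
    of drug-metabolizing enzyme and transporter (DMET) genes in primary human
    hepatocytes. Provides prior knowledge network (PKN) preprocessing (SIF import,
    Boolean gate flattening, feedback removal, compression, AND-gate expansion),
    qPCR delta-delta-Ct fold-change computation and Hill normalization into [0,1],
    a steady-state fuzzy logic simulation engine with normalized Hill transfer
    functions, genetic-algorithm calibration with threshold-based model reduction
    and model-family consensus networks, validation statistics (average-linkage
    clustering, Spearman validation, grouped t-tests, prediction-versus-data
    tables), and a synthetic multi-donor benchmark generator for end-to-end
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    igraph,
    jsonlite,
    ape
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
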