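Package: fanoreg
Title: Inferring Gene Autoregulation from the Fano Factor of Single-Cell
    Expression Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact stationary analysis of birth-death Markov chain models of
    gene expression, Gillespie simulation of single and coupled gene chains,
    a Gamma-based significance test on the sample variance-to-mean ratio
    (Fano factor), and a workflow that combines per-gene VMR tests with the
    structure of a known gene regulatory network to call positive or negative
    autoregulation from single-cell snapshot count data. Includes a
    synthetic-data generator with ground-truth labels for end-to-end
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
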