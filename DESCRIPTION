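Package: ctmi
Title: Causal Discovery in Time Series via Causal Temporal Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Constraint-based discovery of summary causal graphs from
    multivariate time series. Implements the causal temporal mutual
    information (CTMI) measure on window-based representations of time
    series, its k-nearest-neighbour estimator with a local permutation
    test, and two structure-learning algorithms built on it: PCTMI (under
    causal sufficiency, returning a partially directed summary graph) and
    FCITMI (allowing hidden common causes, returning a partial ancestral
    graph). Also ships a structural-equation benchmark generator with
    nonlinear links, sampling-rate decimation, and directed-edge F1
    scoring, so that recovery performance can be measured end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
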