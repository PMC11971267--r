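Package: skillnets
Title: Psychometric Network Analysis of Gross Motor Skill Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates regularized partial-correlation networks of gross motor
    skill scores (Gaussian graphical models fitted by graphical lasso with
    extended-BIC model selection), computes centrality and bridge-centrality
    statistics on the resulting signed weighted networks using absolute edge
    weights and Dijkstra shortest paths, and quantifies their accuracy and
    stability via nonparametric and case-dropping bootstraps with the
    correlation stability coefficient. Includes a generator of synthetic
    TGMD-3-like skill panels with known sparse community-structured precision
    matrices, stratified group comparison by bootstrap confidence-interval
    overlap, and a reproducible stratified pipeline with text-file artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
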