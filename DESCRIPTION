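Package: sentinet
Title: Regularized Partial-Correlation Networks for Social-Media Topic Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates sparse Gaussian graphical models over daily topic
    proportions derived from labeled social-media posts. Provides ingestion of
    post records into day-by-topic proportion series, nonparanormal (rank-based
    inverse normal) correlation matrices, graphical-lasso estimation with
    extended Bayesian information criterion (EBIC) model selection, weighted
    network centrality (strength, closeness, betweenness) with the
    Zhang-Horvath clustering coefficient, nonparametric bootstrap edge
    stability with edge-weight difference tests and the case-drop correlation
    stability (CS) coefficient, and a logistic-normal multinomial simulator
    that generates corpora with a known sparse partial-correlation structure
    for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
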