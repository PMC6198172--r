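Package: glvbag
Title: Microbial Interaction Inference from Longitudinal Relative
    Abundances via Generalized Lotka-Volterra Models and Bagged Stepwise
    Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers signed, directed microbial interaction networks from
    longitudinal relative-abundance data (e.g., 16S surveys or plate
    counts of defined communities). Community dynamics are modelled with
    a generalized Lotka-Volterra system under a shared logistic carrying
    capacity and fitted to relative abundances by Levenberg-Marquardt
    nonlinear least squares. Interaction coefficients are chosen by
    forward stepwise selection under the Bayesian information criterion,
    stabilised by bootstrap aggregation over random train/test partitions
    of the time series; aggregated coefficients are tested against zero
    with one-sample t-tests and significant pairs are classified into the
    six ecological interaction forms (mutualism, competition, parasitism,
    commensalism, amensalism, neutral). Includes a synthetic-data
    generator with known ground-truth parameters, delimited-table I/O,
    and network export (TSV, GraphML, JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    deSolve,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
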