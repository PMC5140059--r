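Package: reactionet
Title: Structure Learning of Stochastic Reaction Networks from Single-Cell Snapshot Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns the topology and rate constants of stochastic mass-action
    chemical reaction networks from single-cell snapshot time series by a
    stepwise sparse-regression procedure (the reactionet lasso): central-moment
    equations derived from the Chemical Master Equation are turned into a
    linear regression problem by gradient matching, a feasible generalized
    least squares step reduces an exhaustively enumerated unary/binary
    candidate reaction library, and an adaptive relaxed lasso solved by ADMM
    with cross-validation, stability selection and BIC-guided backward
    refinement returns a sparse reaction set with rate estimates. Includes an
    exact Gillespie simulator with binomial capture-efficiency measurement
    noise for generating synthetic snapshot ensembles, noise-corrected moment
    estimators, and evaluation utilities for recovered networks.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    pracma,
    deSolve,
    data.table,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
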