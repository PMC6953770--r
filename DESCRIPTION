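Package: ddd
Title: Dynamic Distribution Decomposition for Snapshot Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers a continuous-time Markov rate matrix (a finite
    approximation of the Perron-Frobenius operator) that maps cell-state
    probability distributions across destructively sampled snapshot time
    points, such as mass cytometry time courses.  Each snapshot is encoded
    on a Gaussian-mixture basis, and the rate matrix together with a free
    initial condition is estimated by minimising the mass-matrix-weighted
    mean squared relative prediction error using analytic matrix-exponential
    gradients, with an optional Lasso penalty for sparse transition
    topologies.  Includes eigenfunction analysis, Markov-rate and
    eigenfunction graph visualisation with GraphML/DOT export, split-window
    autonomy diagnostics, and a bistable-potential-well stochastic
    differential equation simulator for generating benchmark snapshot
    series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
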