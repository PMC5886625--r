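Package: zlconn
Title: Directed Effective Connectivity from Zero-Lag Covariances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates directed, signed effective connectivity between
    network nodes from zero-lag covariances of multivariate signals, such as
    parcellated resting-state fMRI time series.  Under a linear interaction
    model the inverse covariance factorizes as C^-1 = B'B with B = I - G up
    to an orthogonal rotation; the rotation is resolved by minimizing the
    off-diagonal L1 norm of the factor by geodesic gradient descent on the
    orthogonal group, which prefers sparse connectivity and exploits
    collider structure to fix edge directions.  Includes an exactly
    discretized Ornstein-Uhlenbeck surrogate simulator with canonical
    hemodynamic response filtering and observation noise, sparse signed
    Erdos-Renyi network generators, ROC/precision-recall/correlation
    evaluation against ground truth, and a benchmark driver for parameter
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
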