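Package: esindy
Title: Ensemble Sparse Identification of Nonlinear Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers governing ordinary and partial differential equations
    from noisy, limited time-series data by sparse regression on a library of
    candidate terms (SINDy), robustified by bootstrap aggregating. Implements
    sequentially thresholded least squares and ridge regression, weak-form
    (integral) PDE identification with compactly supported test functions,
    bagging/bragging/library-bagging ensembles with term inclusion
    probabilities, probabilistic ensemble forecasting, active learning driven
    by ensemble forecast variance, and ensemble-model-based model predictive
    control. Ships synthetic generators for the canonical benchmark systems
    (Lorenz, Lotka-Volterra, inviscid Burgers, Korteweg-de Vries, nonlinear
    Schroedinger, Kuramoto-Sivashinsky, reaction-diffusion) and a bundled
    lynx-hare predator-prey fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    signal,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
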