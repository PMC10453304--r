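Package: chaosesn
Title: Echo-State Reservoir Forecasting of Chaotic Environmental Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a chaotic environment (the Lorenz-96 system), drives a
    randomly connected recurrent network (an echo-state reservoir) with the
    environmental signal, and trains a cross-validated ridge readout to predict
    future environmental states. Includes a Benettin-type estimator of the
    maximal Lyapunov exponent and its divergence doubling time, and an
    experiment layer that runs seeded replicates and parameter sweeps over
    forcing strength, forecast horizon, and reservoir size, summarising test
    R-squared across replicates. Motivated by the question of how a random
    recurrent network can supply the perceptive half of a perception-response
    trait.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
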