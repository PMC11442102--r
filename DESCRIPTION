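Package: cardiofit
Title: Calibration and Uncertainty Quantification for a Lumped-Parameter
    Left-Ventricle and Aorta Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a time-varying elastance model of the left ventricle
    coupled to a single-compartment (Windkessel-type) aorta, and provides the
    full analysis pipeline around it: synthetic pressure-volume data generation
    under iid, heteroskedastic, or serially correlated measurement error; local
    derivative-based sensitivity analysis with influence ranking, correlation
    analysis, and subset selection; profile-likelihood identifiability
    assessment; multistart nonlinear least-squares calibration with AIC/BIC
    subset comparison; adaptive Metropolis MCMC with conjugate noise-variance
    updates; and frequentist and Bayesian parameter and output uncertainty
    quantification (confidence, credible, and prediction bands).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
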