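Package: gutsgof
Title: Goodness-of-Fit Assessment for GUTS Survival Model Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and Bayesian calibration of reduced General
    Unified Threshold models of Survival (GUTS-RED, stochastic-death and
    individual-tolerance variants) under arbitrary piecewise exposure
    profiles; the quantitative goodness-of-fit suite used in environmental
    risk assessment of plant protection products (NRMSE, posterior
    predictive check, survival probability prediction error, Nagelkerke
    pseudo-R2) with metric rescaling and combination; construction of
    time-series and dose-response-curve representations of model fits with
    Wilson intervals; a synthetic visual-assessment survey generator
    (latent cumulative ordinal scores with evaluator random effects); and
    the inference chain relating visual scores to fit metrics: Bayesian
    cumulative ordinal regression, PSIS-LOO predictor screening,
    Bernoulli-logit acceptance modelling with 50%-acceptance threshold
    derivation, and rejection-reason modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
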