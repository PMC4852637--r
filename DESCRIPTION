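Package: abmassim
Title: Dynamic Calibration of Stochastic Agent-Based Models with the
    Ensemble Kalman Filter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequential data assimilation for stochastic agent-based and
    compartmental models of pedestrian activity. Provides exact
    (Gillespie) event-driven simulators for an immigration-death "box"
    process and for the WHIRS shopper/worker compartment model of
    high-street footfall, together with their analytic and
    master-equation oracles; a generic perturbed-observation ensemble
    Kalman filter with virtual observations, state-augmented sequential
    parameter estimation and a log-space positivity transform; a daily
    rate-resampling scheme with particle-filter-style likelihood
    weighting for identifying day-specific rate parameters; hourly
    footfall count input/output, descriptive statistics, observation
    noise models and a synthetic footfall generator; and RMSE scoring
    against standard persistence/seasonal baseline forecasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
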