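Package: steerdyn
Title: Steering Dynamics, Path Integration and Bayesian Time-Constant Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for joystick steering tasks in
    which control dynamics follow a leaky integrator whose time constant
    varies slowly across trials. Provides the closed-form gain calibration
    that equalises nominal travel time across time constants, a log-domain
    AR(1) generator for the time-constant sequence, a synthetic-participant
    generator whose internal estimate of the dynamics is shrunk toward a
    prior, the descriptive behavioural analyses (no-intercept response
    gains, residual errors and their time-constant dependence, interaction
    regressions, a simulated no-adaptation null, joystick-input summaries),
    and a family of internal-model estimators (static and dynamic Bayesian
    prior, fixed estimate, carry-over, sensory feedback control) with
    believed-trajectory reconstruction, least-squares fitting, validation
    and model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    readr,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
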