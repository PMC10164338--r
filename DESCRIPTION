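Package: radtse
Title: Tumor Growth Modelling and Tumor Static Exposure for Radiation
    plus Radiosensitizer Therapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a cell-kill and growth-inhibition model of xenograft
    tumor response to fractionated radiotherapy combined with
    radiosensitizing agents (ATM inhibitors), driven by per-application drug
    concentration.  Radiation acts twice: an instantaneous linear-quadratic
    kill at each fraction and a long-term inhibition of the proliferation
    rate by the accumulated dose; both effects are potentiated by the drug.
    Provides Tumor Static Exposure (TSE) curves computed analytically,
    by simulation for the median individual, and by Monte-Carlo population
    percentiles, for ranking radiosensitizers by the radiation dose they
    save.  Includes a nonlinear mixed-effects population model with
    between-subject and inter-study variability, a synthetic xenograft study
    generator, a Laplace (FOCE-type) population estimator with AIC-based
    selection of the inhibition function, visual-predictive-check summaries,
    and local sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
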