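Package: fluxdebt
Title: Hurricane Impact and Carbon Recovery-Debt Analysis for Mangrove
    Eddy-Covariance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify hurricane impacts on coastal mangrove carbon
    exchange from half-hourly eddy-covariance data. Fits Michaelis-Menten
    light-response and Lloyd-Taylor temperature-response parameters in 24-day
    windows by bounded nonlinear least squares, detects disturbance impacts
    and their duration with a relative non-stationarity statistic, scales
    carbon-exchange parameters across a landscape through leaf area index
    (LAI), and computes annual and cumulative "recovery debt" in carbon units
    at site and landscape scale. Includes a synthetic flux-tower and
    landscape simulator with known ground truth so every stage of the
    pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    readr,
    zoo
Suggests:
    jsonlite,
    knitr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
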