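Package: idiovar
Title: Idiographic Vector Autoregression for Daily Sleep and Depression Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-patient (N-of-1) analysis of daily sleep diaries and
    depression core-symptom self-ratings. Parses raw morning/evening diary
    logs into aligned daily series of time in bed, total sleep time and a
    0-10 depression score, imputes missing days by Kalman smoothing of a
    univariate ARIMA state-space model, differences each series to
    stationarity, fits a bivariate vector autoregression by equationwise
    least squares with AIC lag selection (maximum 7 days), tests Granger
    causality in both directions, and quantifies dynamics via
    orthogonalized impulse-response functions (1-SD shocks, 10-day
    horizon, residual-bootstrap confidence bands) and forecast-error
    variance decomposition. Ships a synthetic-cohort generator with known
    VAR ground truth, and cohort-level aggregation of associations,
    cumulative impulse responses and explained-variance shares.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
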