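Package: gwtlsr
Title: Geographically Weighted Total Least Squares Regression for Land Use
    Regression Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Errors-in-variables spatial regression for land use regression
    (LUR) modelling of air pollutant concentrations. Implements geographically
    weighted total least squares regression (GWTLSR), which solves a weighted
    total least squares problem at every location using Gaussian distance-decay
    kernel weights as the observation covariance, so that both the response and
    the covariates are treated as noisy observations and regression
    coefficients may vary smoothly over space. Also provides the ordinary least
    squares, geographically weighted regression (GWR), and global weighted
    total least squares baselines; AICc-driven bandwidth selection; model
    assessment metrics (R-squared, RMSE, MAE, AICc, percentile-exceedance
    probability of detection and false alarm, residual Moran's I); two-stage
    variable selection with buffer screening; station-wise leave-one-out
    cross-validation; and a synthetic-data generator with known ground truth
    for estimator evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
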