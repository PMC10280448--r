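Package: icgnarx
Title: NARX Neural-Network Forecasting of Impedance-Cardiography Characteristic Points
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for predicting missing characteristic points (A, B, E, X1,
    X2, Y, O, Z) in beat-to-beat impedance-cardiography (ICG) dZ/dt complexes
    from R-peak-anchored interval time series. Implements the full workflow:
    annotated-beat input/output, interval-matrix construction, mean imputation,
    RR-ratio and sum-of-squares normalization, a nonlinear autoregressive
    network with exogenous inputs (NARX; 8 channels, 10 hidden units, delay 2)
    trained open-loop by Levenberg-Marquardt, scaled conjugate gradient or
    Bayesian regularization with validation-based early stopping, closed-loop
    multi-step forecasting with optional delay removal, subtype-aware
    imputation of missing points, X-candidate selection, an evaluation suite
    (MSE, RMSE, MAE, Pearson R, VEcv, Lin's concordance correlation
    coefficient, detection rates), and a synthetic cohort generator for
    validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
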