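Package: eemcalib
Title: Second-Order Fluorescence Calibration by Unfolded PCA and Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies an analyte from excitation-emission matrix (EEM)
    fluorescence landscapes by unfolded principal component analysis coupled
    to a single-hidden-layer backpropagation neural network (UPCA-ANN).
    Provides EEM cube data structures with delimited-text I/O, a bilinear
    EEM simulator with serum-like interferent backgrounds, cube unfolding
    and PCA with variance accounting and score-plot outlier screening,
    Kennard-Stone calibration/validation/test splitting, a from-scratch
    feed-forward network trained by gradient descent with momentum and
    validation-based early stopping, leave-one-out cross-validation for
    factor selection, response-surface hyperparameter scans, and
    multivariate figures of merit (RMSE, REP%, R-squared, LOD/LOQ).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
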