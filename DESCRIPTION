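Package: exposelect
Title: Benchmarking Variable-Selection Methods for Exposome-Health Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for comparing linear-regression-based
    variable-selection methods in an exposome-wide association setting.
    Generates exposure matrices with a realistic correlation structure
    (empirical or surrogate), relates a continuous health outcome to a
    controlled number of true predictors at a fixed signal-to-noise ratio,
    runs six selection methods (univariate screening with multiplicity
    correction, two-stage screening plus multiple regression, elastic net
    with the one-standard-error rule, sparse partial least squares with
    soft thresholding, Bayesian variable selection by evolutionary
    stochastic search, and deletion/substitution/addition model search),
    and scores them with classical and correlation-aware performance
    statistics (sensitivity, specificity, false discovery proportion,
    alternative sensitivity/FDP, mean absolute bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    withr,
    Matrix,
    parallel,
    stats,
    utils,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    readxl,
    jsonlite
Config/testthat/edition: 3
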