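Package: psad2t
Title: Treatment-Difficulty Indexing and Difficult-to-Treat Classification
    for Psoriatic Arthritis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying treatment difficulty in psoriatic
    arthritis (PsA) cohorts treated with biological or targeted-synthetic
    DMARDs. Implements a configurable three-criterion difficult-to-treat
    (D2T) classifier with Firth-penalized univariate logistic associations,
    an observed-versus-expected b/tsDMARD treatment-difficulty index
    calibrated at the cohort 75th percentile of the per-patient failure
    rate, Poisson regression with a log-expected offset and restricted
    cubic spline terms for the relative treatment difficulty, and a
    bootstrap-bagged backward-AIC variable-selection procedure with
    zero-imputed coefficient averaging and nomogram output. A synthetic
    cohort generator with a known count-generating model supports testing
    of every stage without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
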