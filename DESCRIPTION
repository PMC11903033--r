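Package: funflmm
Title: Functional Linear Mixed Models for Trial-Aligned Time-Series Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Function-on-scalar regression with nested random effects for
    trial-aligned time-series signals such as fiber-photometry recordings.
    Fits a Gaussian linear mixed model at every within-trial time-point,
    smooths the resulting coefficient functions with penalized B-splines,
    assembles the cross-time covariance of the smoothed estimators (method
    of moments for the random-effect cross-covariance), and constructs
    analytic pointwise and simulation-based simultaneous 95% confidence
    bands. Includes a synthetic-data generator with Gaussian-process
    functional random effects and temporally correlated trial noise,
    comparator analyses (within-subject permutation test with a
    consecutive-threshold rule, paired t-test and mixed model on
    area-under-the-curve summaries), and a replicated-simulation benchmark
    of coverage and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
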