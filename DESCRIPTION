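Package: akibma
Title: Center-Adjusted Biomarker Combinations via Bayesian Model Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Develops and internally validates center-adjusted biomarker
    combinations for postoperative acute kidney injury. Implements Bayesian
    model averaging for logistic regression with forced-in center effects
    (BIC-approximated posterior model probabilities, Occam's window, maximum
    posterior and median probability selection rules), covariate-adjusted AUC
    estimation, bootstrap optimism correction that repeats the entire
    selection process in every resample, repeated split-sample comparison of
    selection strategies, prognostic-enrichment calculations for clinical
    trial design, and mortality-association analyses for fixed combinations.
    Ships a synthetic multicenter cohort generator that emulates the
    statistical structure of a postoperative biomarker study so the full
    pipeline is exercisable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
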