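Package: twophaseAUC
Title: Inverse-Probability-Weighted AUC Estimation and Comparison in
    Two-Phase Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of the area under the ROC curve (AUC)
    for a binary disease outcome when biomarkers are measured on a biased
    phase-two subsample of a cohort, as in frequency-matched case-control
    studies. Implements inverse-probability-weighted (IPW) AUC and
    difference-in-AUC estimators with estimated or known sampling weights,
    closed-form asymptotic variances and Wald inference for both Bernoulli
    and finite-population stratified sampling, a DeLong-type comparator test,
    a bi-normal synthetic-cohort simulator with both sampling designs, a
    Monte-Carlo study driver for operating characteristics, and analytic
    design-efficiency calculations for comparing control-sampling schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    pROC,
    rlang,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
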