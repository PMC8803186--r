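Package: ctot
Title: Cycle-to-Threshold Analysis of Censored qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-group comparison of qPCR quantification-cycle (Cq) data in
    which some reactions never cross the fluorescence threshold before the
    assay's maximum quality cycle and are reported as "Undetermined". Such
    observations are right-censored at a known cutoff, and the package treats
    normalized Cq (delta-Cq) as a cycle-to-threshold outcome: it provides an
    exact permutation log-rank test with optional Fleming-Harrington weights
    (the CTOT test), the common substitution (MC), complete-observation (CO)
    and choose-not-to-analyze (CNA) strategies with two-sample t-tests, a
    full-data benchmark (BFD) for simulations, interpretable summaries
    (threshold-crossing rate ratio, Kaplan-Meier median delta-Cq, proportion
    uncertain), a delta-Cq simulator under log-normal, Weibull and
    log-logistic families, and Monte Carlo power and type-I-error study
    harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
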