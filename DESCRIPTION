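Package: clqas
Title: Design of Cluster Lot Quality Assurance Sampling Surveys
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and evaluation of cluster lot quality assurance
    sampling (C-LQAS) classification surveys. Computes exact
    misclassification risks for two-stage cluster designs under a
    beta-binomial model indexed by the intraclass correlation, searches
    for the minimal per-cluster sample size and decision rule that bound
    both risks, tabulates design options with per-cluster and
    per-individual costs, produces operating characteristic curves, and
    provides a seeded Monte Carlo engine for sensitivity analysis of
    intraclass-correlation misspecification together with the one-way
    ANOVA estimator of the intraclass correlation for binary outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
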