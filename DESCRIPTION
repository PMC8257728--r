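Package: breathdiscrim
Title: Exhaled-Breath Volatilome Discrimination of Asthma with Coexisting Atopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for discriminating asthma with
    coexisting atopic disease from exhaled-breath volatilome feature tables:
    ambient-air-aware feature screening (named contaminant removal plus paired
    one-sided Wilcoxon signed-rank filtering against room-air samples),
    ANOVA-simultaneous component analysis (ASCA) to remove season and
    residence-zone batch variation, L1-penalized logistic regression with
    fivefold cross-validated penalty selection, permutation-test model
    significance, prevalence-based classification cutoffs and external
    validation-set evaluation. Includes subject-characteristics statistics
    (normality-gated group comparisons and categorical association tests) and a
    seeded synthetic breath-cohort generator with planted discriminant
    compounds, batch effects, paired ambient samples and clinical covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
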