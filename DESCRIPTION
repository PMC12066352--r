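Package: nettemp
Title: Network Temperature Estimation for Longitudinal Binary Symptom Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multigroup Ising models for panels of binarized symptom data,
    with an inverse-temperature (dependence) parameter identified across
    measurement occasions. Provides exact enumeration-based likelihoods for
    small item sets, Gibbs entropy, equality-constrained multigroup maximum
    likelihood with dense and pruned (sparse) structures, fit-index model
    selection (AIC, BIC, RMSEA, chi-squared), analytic and case-bootstrap
    confidence intervals for network temperature, stratified trajectory
    comparison, and a seedable synthetic cohort generator so the whole
    pipeline is testable without access-restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    withr,
    generics,
    lme4,
    lmerTest,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
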