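Package: svygap
Title: Survey-Weighted Decomposition of Group Disparities in Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based tools for quantifying and explaining rural-urban (or any
    two-group) disparities in a binary outcome measured by complex multi-country
    household surveys such as the Demographic and Health Surveys. Provides
    survey-weighted prevalence estimation with Taylor-linearized standard errors,
    random-effects pooling of country estimates for forest plots, Rao-Scott
    design-adjusted chi-square tests, variance-inflation-factor screening,
    survey-weighted logistic regression with stratified cluster-robust covariance,
    and a multivariate non-linear (logit) Blinder-Oaxaca-type decomposition of the
    group gap into characteristics (endowment) and coefficients components with
    normalized per-category detailed contributions and a PSU bootstrap for
    uncertainty. Includes a synthetic two-stage cluster survey generator with an
    exact enumeration oracle for the population decomposition, and a config-driven
    pipeline that reproduces the full descriptive/regression/decomposition output
    surface from a CSV and a YAML file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    metafor,
    readr,
    rlang,
    statmod,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
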