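Package: skewpower
Title: Sample Size and Power for Comparing Means of Skewed Outcomes via
    Generalized Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-size formulas for comparing two group means of skewed
    outcome variables (negative binomial, Poisson, binomial, gamma) derived
    from generalized linear model theory on the scale of the link function,
    together with two diagnostics of normal-approximation error for discrete
    sums (Berry-Esseen bounds with numerically computed absolute third
    central moments, and the exact maximum discrepancy between the CDF of a
    standardized iid sum and the standard normal CDF), and a seeded
    Monte-Carlo engine that verifies achieved power and type-I error by
    fitting two-group GLMs and applying Wald and likelihood-ratio tests.
    Motivated by trial endpoints such as heavily overdispersed parasite egg
    counts and right-skewed insecticide concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
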