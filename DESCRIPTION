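Package: trionurture
Title: Decomposing Parental Polygenic-Score Associations into Genetic
    Transmission and Genetic Nurture in Trio Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trio (mother-father-child) polygenic-score analyses of
    ordinal child outcomes. Simulates trio cohorts with known direct, genetic
    transmission and genetic nurture effects (Mendelian transmission, optional
    assortative mating, population stratification and item missingness);
    performs summary-statistic QC, polygenic scoring, covariate
    residualization and relatedness filtering; estimates thresholds,
    polychoric and polyserial correlations and ordinal reliability; fits a
    latent-factor trio structural equation model by weighted least squares on
    the mixed correlation matrix with family-bootstrap or linearized standard
    errors; decomposes parental associations into transmission (a x beta_C)
    and nurture paths with Benjamini-Hochberg multiplicity correction; and
    runs Monte-Carlo power analyses for transmission and nurture tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
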