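Package: sempath
Title: Structural Equation Modeling of SNPs, Intermediate Phenotypes, and
    Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A four-step pipeline relating multiple SNPs, latent genetic
    factors, obesity-related intermediate phenotypes, and correlated diseases
    (type 2 diabetes and hypertension) through structural equation models.
    Step 1 screens SNPs by single-marker linear or logistic regression with
    demographic covariates and groups the significant markers into per-trait
    SNP blocks. Step 2 summarises each block by exploratory factor analysis
    with varimax rotation, communality filtering, and standardized factor
    scores. Step 3 estimates covariate-adjusted partial correlations among
    phenotypes and fits a recursive path model that fixes the mediation
    ordering. Step 4 fits the full structural model by maximum-likelihood
    covariance-structure estimation, computes fit indices (NFI, CFI, GFI,
    AGFI, RMSEA), and decomposes standardized effects into direct, indirect,
    and total components with delta-method standard errors. A synthetic
    cohort generator with Hardy-Weinberg genotypes, correlated SNP groups,
    a trait cascade, and liability-threshold diseases makes every stage
    testable without access to restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
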