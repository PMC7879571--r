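Package: gaitlong
Title: Gait Traits and Functional Longevity in Sport Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links early gait traits of young jumping horses to functional
    longevity in competition. Implements a discrete-time proportional-hazards
    survival model with correlated sire and maternal-grandsire effects,
    deregression of the resulting breeding values into weighted
    pseudo-phenotypes, pedigree and genomic relationship matrices combined by
    single-step GBLUP, constrained bivariate REML for genetic correlations
    between gait principal components and longevity, and a SNP-effect
    back-solution genome-wide association study. Includes simulators for
    pedigrees, genotypes (gene dropping), competition careers and repeated
    gait records with known true parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    Matrix,
    methods,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
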