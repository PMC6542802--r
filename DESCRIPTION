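Package: deathcue
Title: Statistics for Death-Perception Experiments in Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for experiments on the perception of dead
    conspecifics in Drosophila melanogaster. Implements chooser-weighted
    preference indices and randomization tests for binary T-maze assays,
    a targeted head-metabolome pipeline (missingness filtering, log
    transformation, k-nearest-neighbour imputation, standardization, PCA,
    and a permutation-calibrated between/within-variance Z score that finds
    principal components separating treatment groups), a two-criterion
    candidate-metabolite screen, survival comparisons (Kaplan-Meier,
    log-rank, Cox and age-at-death ANOVA interaction tests), and seeded
    synthetic-data generators that emulate the statistical structure of
    each assay for calibration and parameter-recovery studies.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
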