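Package: glload
Title: Glycemic Response Analysis and Glycemic Load Prediction for Mixed Meals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing postprandial glycemic response data from
    mixed-meal feeding studies. Computes incremental area under the curve
    (iAUC) from fingertip glucose trajectories, per-participant glycemic
    index (GI) against carbohydrate-matched sugar references, and glycemic
    load (GL); applies the study exclusion rules; fits a repeated-measures
    mixed model of iAUC on nutrient composition and a linear GL-on-iAUC
    bridge; composes the two into a nutrition-label GL prediction formula;
    and validates predictions against measured GL. A synthetic-study
    generator emulates the crossover feeding design so the whole pipeline
    runs, and is testable, without access to individual-level data.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
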