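Package: phagestress
Title: Decay and Damage Analysis of Bacteriophage Particles Under
    Environmental Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy analysis pipeline for quantifying bacteriophage
    particle decay and damage under environmental stressors (heat, urea,
    saline). Converts plaque-assay counts to PFU/mL titers with
    limit-of-detection censoring, normalizes to percent survival against
    configurable reference treatments, fits stratified log-linear decay
    models with one-tailed Bonferroni-adjusted slope tests and sequential
    ANCOVA tables, and extracts a growth-curve-derived phage-fitness
    statistic (first local maximum of smoothed bacterial OD600) compared
    across treatments by ANOVA with Tukey HSD compact letters and a Welch
    control contrast. Includes a synthetic-data generator that emulates
    the full measurement process: exponential (optionally biphasic)
    virion decay observed through Poisson plaque counting with serial
    dilutions, and phage-bacteria growth dynamics integrated from a
    stage-structured infection model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    deSolve,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
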