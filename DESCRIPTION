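Package: ecscreen
Title: Cost-Effectiveness Modelling of One-Time Esophageal Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort state-transition model of one-time endoscopic
    screening for esophageal squamous cell carcinoma, with eleven health
    states, three screening strategies and six starting-age cohorts.
    Provides the full economic evaluation workflow: calibration of annual
    transition probabilities from published rates, deterministic cohort
    simulation to age 79, discounted cost and QALY accumulation, ICER and
    dominance analysis, one-way (tornado) sensitivity analysis and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves and confidence ellipses. Results are returned as
    tibbles and plotted with ggplot2.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
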