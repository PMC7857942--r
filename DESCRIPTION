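Package: ecohortr
Title: Adherence, Scoring, and Agreement Analysis for Smartphone-Survey eCohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal smartphone-app survey data from
    digital (eCohort) studies embedded in clinic-based cohorts. Assigns
    returned surveys to 90-day protocol windows, computes completion and
    adherence metrics under a 75% item-completion rule, scores the Physical
    Activity Index, CES-D depressive symptoms, and weekly alcohol consumption
    with standard missing-item imputation rules, and quantifies app-versus-
    clinic agreement with Lin's concordance correlation coefficient,
    Cohen's kappa, and Bland-Altman limits of agreement. Includes group
    comparisons, an adjusted logistic model of returner characteristics,
    balanced random-intercept trend models, and a synthetic eCohort
    generator so every stage of the pipeline is testable without access to
    participant-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
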