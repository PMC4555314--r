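Package: icfmonitor
Title: Monitoring and Prognosis of Functioning Profiles with the ICF
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Standardizes heterogeneous rehabilitation questionnaires
    (Barthel index, CIQ, PCRS and related instruments) into longitudinal
    profiles coded with the WHO International Classification of
    Functioning, Disability and Health (ICF): declarative item and value
    crosswalks, cross-instrument aggregation, and hierarchical inference
    of missing parent categories. Provides individual and population
    monitoring representations with the standard severity colour coding,
    a clinical-decision-support benchmark that predicts the next
    qualifier of a target category from two temporal feature
    representations, socio-economic burden indicators (QALYs gained,
    DALYs averted, savings), and a synthetic cohort generator emulating
    the demographic and missingness structure of an acquired brain
    injury rehabilitation registry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils,
    class,
    e1071,
    rpart,
    ranger
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
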