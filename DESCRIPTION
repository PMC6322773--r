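Package: weightape
Title: Virtual Validation of Paediatric Weight-Estimation Tapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for "virtual" validation studies of length- and
    habitus-based paediatric weight-estimation systems (PAWPER XL-MAC,
    Broselow tape editions, the Ralston three-tape method) on anthropometric
    survey records of children aged 6 to 59 months. Provides LMS
    growth-reference z-scoring and classification, calibration-table-driven
    tape estimators with validated loaders, the standard weight-estimation
    accuracy framework (mean percentage error, Bland-Altman 95% limits of
    agreement, root mean square percentage error, p10/p20 accuracy
    proportions, and their normal-integral imputation from printed summary
    statistics), paired McNemar and matched odds-ratio comparisons between
    systems, a subgroup reporting pipeline, and a synthetic cohort simulator
    so every stage is testable without the source survey dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    stats,
    generics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
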