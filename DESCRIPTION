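Package: sadedup
Title: Distinguish Distinct Suicide Attempt Events Among Recurrent EHR
    Diagnosis Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding when recurrent suicide-attempt ICD-9/ICD-10-CM
    diagnosis codes in longitudinal electronic health record (EHR) data refer
    to distinct suicide attempt events rather than follow-up coding of a single
    event. Implements a validated code-based case definition with
    character-position intent rules, day-level aggregation of coded encounters,
    construction of consecutive code pairs, positive-predictive-value (PPV)
    estimation with unclipped Wald confidence intervals by clinical setting,
    attempt method and intercode interval, derivation of interval-floor
    deduplication rules at a PPV benchmark, application of such rules to
    unlabeled code streams, and a synthetic labeled cohort generator that
    emulates the cascade structure of real encounter data for end-to-end
    testing. Intended to prevent outcome data leakage when prior attempts are
    used as predictors in EHR-based suicide risk prediction models.
License: MIT
Encoding: UTF-8
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
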