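Package: decodr
Title: Subject-Level Brain-Behavior Decoding with Repeated Random Splits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trial-level decoding of behavioral measures (reaction time and
    confidence) from single-trial fMRI activation averaged within cortical
    parcels, one region and one subject at a time. Implements repeated
    random-split cross-validation with Fisher-aggregated Pearson performance,
    permutation-null significance, a multi-level Bonferroni significance
    ledger, group-level one-tailed t-tests, coverage summaries, a
    trial-number sufficiency test based on whole-brain minimum-norm
    multilinear regression, and detection of regions whose activation-behavior
    slope has opposite signs in different subjects. Ships a synthetic cohort
    generator with planted, analytically checkable per-subject per-region
    couplings for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
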