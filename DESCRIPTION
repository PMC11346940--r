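Package: adcmine
Title: Tumor-Selective Antibody-Drug-Conjugate Target and Payload Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-silico discovery pipeline for antibody-drug conjugate (ADC)
    development. Prioritizes tumor-selective target antigens from
    immunohistochemistry, transcriptomic and surfaceome evidence through a
    nine-stage filtering cascade built around the quasi H-score (a 0-300
    summary of staining-level patient fractions); screens how somatic
    mutations in query genes modulate target expression across tumor cohorts
    with a Wilcoxon rank-sum test gated on fold change and mutation
    prevalence; mines cytotoxic-compound GI50 screening data for
    tumor-selective payload candidates in picomolar and low-nanomolar potency
    windows with hierarchical clustering of per-indication response profiles;
    and joins the two arms into target-indication-payload combinations. A
    synthetic-cohort generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
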