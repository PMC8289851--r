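Package: hemrisk
Title: Obstetric Hemorrhage Risk Stratification and Screening Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based stratification of deliveries into low, medium and
    high obstetric-hemorrhage risk tiers following the AWHONN three-tier
    risk-assessment item set, derivation of a composite hemorrhage-related
    maternal morbidity outcome (estimated blood loss >= 1000 mL, any packed
    red-blood-cell transfusion, ICU admission, hysterectomy or dilation and
    curettage), and screening-test evaluation of the tiers against that
    outcome: 2x2 contingency tables per risk contrast with sensitivity,
    specificity, predictive values, and diagnostic odds ratios with Woolf
    (log-normal) confidence intervals and Haldane-Anscombe correction.
    Includes a seed-reproducible synthetic delivery-cohort generator
    calibrated to published group sizes and per-group outcome rates, and a
    pipeline that runs ingest, classification, scoring and evaluation end
    to end with CSV and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
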