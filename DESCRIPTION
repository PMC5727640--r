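Package: apatinibCEA
Title: Cost-Effectiveness and Budget-Impact Model of Third-Line Apatinib
    for Metastatic Gastric Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A partitioned-survival cohort model of third-line apatinib
    versus supportive care in chemotherapy-refractory metastatic gastric
    cancer, from a health-insurance payer perspective. Weibull curves are
    fitted to Kaplan-Meier survival points on the complementary log-log
    scale and adjusted by pooled hazard ratios; a weekly three-state trace
    (progression-free, progressed, dead) accrues discounted life-years,
    quality-adjusted life-years and payer costs, including a patient
    assistance programme in which patients pay only an initial period of
    drug. The package computes incremental cost-effectiveness ratios,
    one-way (tornado) sensitivity analyses, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and a five-year
    budget-impact projection, together with synthetic-data generators for
    censored survival cohorts and trial-level hazard-ratio estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    metafor,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
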