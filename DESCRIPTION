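Package: ipicea
Title: Cost-Effectiveness of Ipilimumab Plus Anti-PD-1 Rechallenge in
    Metastatic Melanoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A partitioned-survival cohort model comparing ipilimumab plus
    anti-PD-1 (nivolumab or pembrolizumab) with ipilimumab alone as second-line
    therapy for metastatic melanoma resistant to anti-PD-(L)1 monotherapy, from
    the US payer perspective. Provides log-logistic (and five other parametric)
    survival extrapolation with hazard-ratio adjustment, Kaplan-Meier
    pseudo-individual-patient-data reconstruction and maximum-likelihood
    refitting with AIC selection, a three-week-cycle discounted cohort trace,
    FDA-label drug costing, incremental cost-effectiveness ratios, one-way
    (tornado) and probabilistic sensitivity analyses with cost-effectiveness
    acceptability curves, and subgroup analyses, plus a synthetic-data module
    for end-to-end testing of the curve-reconstruction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
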