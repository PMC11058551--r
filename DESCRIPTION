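Package: cohortpower
Title: Monte Carlo Power Analysis for Weibull Proportional-Hazards Cohort Studies
Version: 0.1.0
Authors@R:
    person("cohortpower", "developers", email = "cohortpower@example.org",
           role = c("aut", "cre"))
Description: Design time-to-event cohort studies by simulation. Generates
    synthetic cohorts from a confounder -> exposure -> Weibull-survival
    data-generating mechanism with administrative censoring, fits the Weibull
    proportional-hazards model by maximum likelihood with Wald tests and
    confidence intervals on the hazard-ratio scale, and replicates the
    generate-fit-test cycle to estimate statistical power, type-I error,
    sampling distributions of hazard ratios, and survival-curve variability.
    Ships a worked example: physical activity and 10-year mortality in a
    cohort of older people.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
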