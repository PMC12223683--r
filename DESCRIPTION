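Package: ladose
Title: Maximum Safe Local Anesthetic Doses and Dose-Recommendation Safety Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a comprehensive rule set for computing maximum safe
    doses of local anesthetics (ideal body weight by the Devine formula,
    BMI-gated calculation weight capped at 70 kg, and metabolic risk-factor
    dose reductions), together with an evaluation pipeline that grades
    candidate dose recommendations against reference doses (overdose
    classification, percent and absolute exceedance summaries), ordinal
    consensus ratings with inter-rater reliability (Cronbach alpha), and a
    seeded synthetic clinical-vignette generator with simulated respondents
    for end-to-end testing. Bundles the per-vignette dose table and
    consensus ratings from a published evaluation of three conversational
    AI chatbots so that its summary statistics can be recomputed from
    scratch. Research use only; not a medical device.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
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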