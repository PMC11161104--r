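Package: emadhere
Title: Electronic-Monitor Dosing Histories: Implementation, Persistence
    and Adherence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing medication adherence to oral anticancer
    therapies measured with electronic monitors (EM). Builds a day-level
    dosing-history database from EM opening logs and prescription records
    (03:00-to-02:59 day boundary, truncation to the monitored window,
    pocket-dose correction confirmed by pill counts, nonmonitored-period
    masking), reconciles oncologist-prescribed regimens (including transient
    interruptions and cyclic schedules) against the manufacturer's on-label
    regimen, and estimates the three adherence phases: daily implementation
    via generalized estimating equations with an autoregressive working
    correlation and time-dependent exposure covariates, persistence via
    Kaplan-Meier curves, and composite adherence as their product. Includes
    a calibrated synthetic-cohort generator for end-to-end testing, scoring
    of the Beliefs about Medicines Questionnaire and the EORTC QLQ-C30, and
    publication-shaped tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    lubridate,
    purrr,
    rlang (>= 1.0.0),
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
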