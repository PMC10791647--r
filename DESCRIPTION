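Package: qexposure
Title: Quarterly Exposure-to-Risk and Sub-Annual Demographic Summaries
    from Vital-Registration Microdata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns individual-level demographic microdata (dates of birth,
    dates of events, sex) into sub-annual summary datasets: quarterly
    age-by-calendar event counts and exposure/non-exposure times on the
    Lexis plane, moving-average daily series with confidentiality
    suppression, weekday tabulations, and January-1 date-heaping
    correction. Includes a synthetic vital-registration generator with
    known ground-truth parameters (birth seasonality, weekend birth
    deficit, Gompertz mortality with winter excess, autumn migration
    peak, date heaping) so every pipeline stage can be validated without
    confidential source data, plus internal-consistency validation
    reports reconciling event counts against exposure times.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
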