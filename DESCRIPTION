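Package: oppcost
Title: Opportunity-Cost Valuation of Hospital Bed-Days
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A costing engine for the opportunity cost of hospital bed-days.
    Implements a four-methodology taxonomy of bed-day valuation (units of the
    second-best alternative forgone; net benefit of the second-best alternative
    forgone; expenditure of the chosen alternative; chosen expenditure plus the
    highest net benefit forgone), fourteen estimators spanning patient- and
    treatment-equivalents, expenditure, revenue, gross and net monetary or
    health benefit, case-mix ranking with second-best identification, an
    optimality assessment that selects the appropriate methodology, occupancy
    and exogenous-shock adjustments, case-mix file input/output, and a seeded
    synthetic case-mix generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
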