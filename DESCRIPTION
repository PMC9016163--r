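Package: obesim
Title: Agent-Based Life-Course Microsimulation of Obesity and Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time agent-based microsimulation of a closed birth
    cohort nested in neighborhoods, advanced through ten critical life
    stages by lagged logistic and linear behavior and outcome equations
    with body-mass-index feedback on physical activity. Includes synthesis
    of neighborhood and agent populations, LMS-based child BMI z-scores and
    weight-status classification, cohort epidemiologic measures (person-time
    incidence rates, cumulative incidence, age-specific incidence,
    prevalence, with Wald confidence intervals), calibration-in-the-large by
    sequential per-stage grid search against observed age-band means and
    proportions, and counterfactual intervention scenarios contrasted
    against the natural course with common random numbers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
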