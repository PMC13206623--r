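Package: psocap
Title: Capacity and Staffing-Ratio Planning for Psychosocial Oncology Programs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Canadian Association of Psychosocial Oncology (CAPO)
    staffing framework as a parameterized demand-capacity planning engine for
    psychosocial oncology (PSO) and supportive-care programs. From a work-hours
    calendar and a discipline profile it computes the annual caseload capacity
    and direct-patient-care contacts of one full-time-equivalent (FTE) position,
    converts cancer-program incidence into referral demand via a prevalence-of-
    distress rate, and derives required FTE staffing ratios and program-level
    totals. Includes packaged social-work tertiary-center defaults, YAML/JSON
    profile round-tripping, sensitivity sweeps, a stochastic referral-stream
    simulator that validates the deterministic model, and a synthetic
    workload-measurement log generator with aggregation.
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
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
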