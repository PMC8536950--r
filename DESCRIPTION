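Package: adcea
Title: Patient-Level Microsimulation for Cost-Effectiveness of Alzheimer
    Disease Treatment with Caregiver Spillovers
Version: 0.1.0
Authors@R:
    person("adcea", "developers", email = "adcea@example.org", role = c("aut", "cre"))
Description: A patient-level (microsimulation) health-economic model of
    Alzheimer disease progression from mild cognitive impairment through
    severe dementia and death, with a hypothetical disease-modifying
    treatment acting on the CDR Sum-of-Boxes change rate. Provides
    synthetic cohort generation, a monthly-cycle progression engine with
    severity staging on the MMSE, mortality and institutionalization
    hazards, EQ-5D-style patient and caregiver utilities, stage-specific
    cost accounting, 3 percent annual discounting, and an incremental
    cost-effectiveness (ICER) engine that evaluates six analytic
    perspectives -- from a narrow health-care-sector view to a broad
    societal view including caregiver quality of life and productivity --
    on a single set of treated/untreated trajectory pairs simulated with
    common random numbers, plus one-time-versus-repeated treatment
    pricing scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
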