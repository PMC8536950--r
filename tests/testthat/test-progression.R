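mild_state <- function(mmse = 30, cdrsb = 5, npi = 0) {
  patient_state(age = 70, mmse = mmse, cdrsb = cdrsb, npi = npi,
                converted = TRUE, on_treatment = TRUE)
}

run_cycles <- function(state, k, params, on_drug) {
  for (i in seq_len(k)) state <- step_progression(state, params, on_drug = on_drug)
  state
}

test_that("the treatment effect scales the CDR-SB change linearly over cycles", {
  params <- progression_params()  # mild: 1.6 points/year
  st0 <- mild_state()
  untreated <- run_cycles(st0, 18, params, on_drug = FALSE)
  treated <- run_cycles(st0, 18, params, on_drug = TRUE)
  expect_equal(untreated$cdrsb - st0$cdrsb, 2.4, tolerance = 1e-9)
  expect_equal(treated$cdrsb - st0$cdrsb, 1.8, tolerance = 1e-9)
  # exact proportionality when stage and treatment status are fixed
  expect_equal((treated$cdrsb - st0$cdrsb) / (untreated$cdrsb - st0$cdrsb),
               1 - params$treatment_effect, tolerance = 1e-12)
  # MMSE moves through the coupling
  expect_equal(st0$mmse - untreated$mmse,
               params$mmse_per_cdrsb * 2.4, tolerance = 1e-9)
})

test_that("a null treatment effect makes treated and untreated steps identical", {
  params <- progression_params(treatment_effect = 0)
  st0 <- mild_state(mmse = 24, cdrsb = 6, npi = 4)
  expect_identical(run_cycles(st0, 24, params, on_drug = TRUE),
                   run_cycles(st0, 24, params, on_drug = FALSE))
})

test_that("scores are clamped to their scale bounds and dead patients are rejected", {
  params <- progression_params()
  low <- patient_state(age = 88, mmse = 0.5, cdrsb = 17.9, npi = 140,
                       converted = TRUE)
  st <- run_cycles(low, 36, params, on_drug = FALSE)
  expect_gte(st$mmse, 0)
  expect_lte(st$cdrsb, 18)
  expect_equal(st$cdrsb, 18)
  dead <- mild_state(); dead$alive <- FALSE
  expect_error(step_progression(dead, params), "dead")
})

test_that("monthly discontinuation compounds exactly to the annual rate", {
  params <- progression_params(annual_discontinuation = 0.10)
  p <- discontinuation_p_cycle(params)
  expect_equal(p, 1 - 0.9^(1 / 12), tolerance = 1e-15)
  expect_lt(abs((1 - (1 - p)^12) - 0.10), 1e-12)
  expect_true(sample_discontinuation(params, 0.001))
  expect_false(sample_discontinuation(params, 0.999))
  none <- progression_params(annual_discontinuation = 0)
  expect_false(any(vapply(seq(0, 0.999, by = 0.1), function(u)
    sample_discontinuation(none, u), logical(1))))
})

test_that("the stopping rule halts treatment at moderate dementia and is idempotent", {
  params <- progression_params()
  moderate <- patient_state(age = 75, mmse = 18, cdrsb = 9, converted = TRUE,
                            on_treatment = TRUE)
  expect_false(apply_stopping_rule(moderate, params)$on_treatment)
  mci <- patient_state(age = 70, mmse = 27, cdrsb = 2, on_treatment = TRUE)
  expect_true(apply_stopping_rule(mci, params)$on_treatment)
  severe_off <- patient_state(age = 80, mmse = 9, cdrsb = 15, converted = TRUE,
                              on_treatment = FALSE)
  expect_identical(apply_stopping_rule(severe_off, params),
                   apply_stopping_rule(apply_stopping_rule(severe_off, params), params))
})

test_that("severity staging follows the MMSE bands and the conversion flag", {
  expect_identical(assign_severity(18, TRUE), "moderate")
  expect_identical(assign_severity(26, FALSE), "MCI")
  expect_identical(assign_severity(14, TRUE), "severe")
  expect_identical(assign_severity(15, TRUE), "moderate")
  expect_identical(assign_severity(20, TRUE), "moderate")
  expect_identical(assign_severity(21, TRUE), "mild")
  expect_error(assign_severity(31, TRUE), "out of range")
  expect_error(assign_severity(-1, TRUE), "out of range")
  # severity is a non-increasing function of MMSE at fixed conversion
  grid <- seq(0, 30, by = 0.25)
  idx <- match(vapply(grid, assign_severity, character(1),
                      converted_to_dementia = TRUE),
               c("MCI", "mild", "moderate", "severe"))
  expect_true(all(diff(idx) <= 0))
})

test_that("treated CDR-SB never exceeds untreated CDR-SB under common random numbers", {
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_config(n = 1, seed = seed))
    pp <- simulate_patient_pair(coh, seed = seed)
    expect_true(all(pp$treated$cdrsb <= pp$untreated$cdrsb + 1e-12))
  }
})
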