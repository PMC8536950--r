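test_that("patient utility follows the additive regression with clamping", {
  m <- utility_model()
  best <- patient_state(age = 73, mmse = 30, cdrsb = 0.5, npi = 0)
  expect_equal(patient_utility(best, m), 0.408 + 0.010 * 30 + 0.051,
               tolerance = 1e-12)
  worst <- patient_state(age = 85, mmse = 10, cdrsb = 16, npi = 20,
                         converted = TRUE, location = "residential")
  # 0.408 + 0.100 - 0.800 - 0.159 < 0, clamped at the floor
  expect_equal(patient_utility(worst, m, has_caregiver = FALSE), 0)
  # non-decreasing in MMSE, all else fixed
  u <- vapply(seq(0, 30, by = 1), function(mm)
    patient_utility(patient_state(age = 75, mmse = mm, cdrsb = 9,
                                  converted = TRUE, npi = 5), m),
    numeric(1))
  expect_true(all(diff(u) >= 0))
  dead <- best; dead$alive <- FALSE
  expect_error(patient_utility(dead, m), "dead")
})

test_that("caregiver utility uses the severity band in the community and the norm after institutionalization or death", {
  m <- utility_model()
  dem <- patient_state(age = 78, mmse = 18, cdrsb = 9, converted = TRUE)
  expect_equal(caregiver_utility(dem, caregiver_age = 75, m), 0.84)
  mci <- patient_state(age = 73, mmse = 27, cdrsb = 2)
  expect_equal(caregiver_utility(mci, caregiver_age = 70, m), 1.00)
  mild <- patient_state(age = 75, mmse = 24, cdrsb = 6, converted = TRUE)
  expect_equal(caregiver_utility(mild, caregiver_age = 70, m), 0.85)
  sev <- patient_state(age = 85, mmse = 8, cdrsb = 16, converted = TRUE)
  expect_equal(caregiver_utility(sev, caregiver_age = 80, m), 0.82)
  inst <- dem; inst$location <- "residential"
  expect_equal(caregiver_utility(inst, caregiver_age = 72, m), 0.84)  # 65-74 norm
  expect_equal(caregiver_utility(inst, caregiver_age = 80, m), 0.80)
  expect_equal(caregiver_utility(inst, caregiver_age = 60, m), 0.87)
  dead <- dem; dead$alive <- FALSE
  expect_equal(caregiver_utility(dead, caregiver_age = 72, m), 0.84)
})

test_that("utility model validation enforces the band ordering", {
  expect_error(utility_model(caregiver_dementia_utility = c(
    b21_26 = 0.8, b15_20 = 0.84, b0_14 = 0.82)), "decreasing")
})

test_that("QALY accrual discounts at the configured annual rate", {
  expect_equal(accrue_qalys(rep(1, 12), discount_rate = 0), 1.0, tolerance = 1e-12)
  expect_equal(accrue_qalys(1, cycles = 12, discount_rate = 0.03),
               (1 / 12) / 1.03, tolerance = 1e-12)
  expect_equal(accrue_qalys(numeric(0)), 0)
  expect_error(accrue_qalys(rep(1, 3), discount_rate = -0.01), "discount_rate")
  expect_error(accrue_qalys(c(0.5, 1.2)), "weights")
  # discounting never increases the total; equality only at rate zero
  for (seed in 1:5) {
    set.seed(seed)
    w <- stats::runif(60)
    expect_lt(accrue_qalys(w, discount_rate = 0.03),
              accrue_qalys(w, discount_rate = 0))
    expect_equal(accrue_qalys(w, discount_rate = 0), sum(w) / 12,
                 tolerance = 1e-12)
  }
})
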