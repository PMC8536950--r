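test_that("cycle costs read the stage table, price the drug, and zero caregiver components in residential care", {
  tab <- cost_table()
  pricing <- drug_pricing()
  moderate <- patient_state(age = 78, mmse = 18, cdrsb = 9, converted = TRUE,
                            on_treatment = TRUE)
  b <- cycle_costs(moderate, tab, pricing)
  expect_equal(unname(b$components["patient_healthcare"]), 1833)
  expect_equal(unname(b$components["patient_nonhealthcare"]), 611)
  expect_equal(unname(b$components["caregiver_healthcare"]), 748)
  expect_equal(unname(b$components["caregiver_productivity"]), 3019)
  expect_equal(unname(b$components["drug"]), 16000 / 12, tolerance = 1e-12)
  expect_equal(b$total, sum(b$components), tolerance = 1e-9)

  mci <- patient_state(age = 72, mmse = 27, cdrsb = 2)
  b2 <- cycle_costs(mci, tab, pricing)
  expect_equal(b2$total, 1174 + 207 + 705 + 925)
  expect_equal(unname(b2$components["drug"]), 0)

  sev <- patient_state(age = 85, mmse = 8, cdrsb = 16, converted = TRUE,
                       location = "residential")
  b3 <- cycle_costs(sev, tab, pricing)
  expect_equal(unname(b3$components["caregiver_healthcare"]), 0)
  expect_equal(unname(b3$components["caregiver_productivity"]), 0)
  expect_equal(unname(b3$components["patient_healthcare"]), 2105)
  expect_equal(unname(b3$components["patient_nonhealthcare"]), 1025)

  dead <- mci; dead$alive <- FALSE
  expect_error(cycle_costs(dead, tab, pricing), "dead")
})

test_that("one-time charges apply in full at cycle zero and only in one_time mode", {
  ot <- drug_pricing(mode = "one_time", one_time_price = 100000)
  expect_equal(one_time_charge(ot), 100000)
  expect_error(one_time_charge(drug_pricing(mode = "repeated")), "one_time")
  # discounting a cycle-0 charge is the identity
  b <- accrue_costs(
    data.frame(drug = 100000, patient_healthcare = 0, patient_nonhealthcare = 0,
               caregiver_healthcare = 0, caregiver_productivity = 0),
    cycles = 0, discount_rate = 0.03)
  expect_equal(unname(b$components["drug"]), 100000)
})

test_that("cost accrual discounts component-wise and is linear", {
  one <- data.frame(drug = 0, patient_healthcare = 1200, patient_nonhealthcare = 0,
                    caregiver_healthcare = 0, caregiver_productivity = 0)
  b <- accrue_costs(one, cycles = 12, discount_rate = 0.03)
  expect_equal(unname(b$components["patient_healthcare"]), 1200 / 1.03,
               tolerance = 1e-12)
  set.seed(8)
  stream <- data.frame(drug = stats::runif(24, 0, 1400),
                       patient_healthcare = stats::runif(24, 0, 2000),
                       patient_nonhealthcare = stats::runif(24, 0, 1000),
                       caregiver_healthcare = stats::runif(24, 0, 800),
                       caregiver_productivity = stats::runif(24, 0, 5000))
  undisc <- accrue_costs(stream, discount_rate = 0)
  expect_equal(unname(undisc$components), unname(colSums(stream)),
               tolerance = 1e-9)
  disc <- accrue_costs(stream, discount_rate = 0.03)
  expect_equal(disc$total, sum(disc$components), tolerance = 1e-9)
  expect_lt(disc$total, undisc$total)
})

test_that("cost table validation enforces sign and severity monotonicity", {
  expect_error(cost_table(patient_healthcare = c(MCI = -5, mild = 1377,
                                                 moderate = 1833, severe = 2105)),
               "patient_healthcare")
  expect_error(cost_table(caregiver_productivity = c(MCI = 925, mild = 925,
                                                     moderate = 3019, severe = 5055)),
               "increasing")
  expect_error(drug_pricing(annual_price = -1), "annual_price")
})
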