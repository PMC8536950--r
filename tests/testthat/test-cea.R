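small_pairs <- function(n = 200, seed = 9, ...) {
  coh <- generate_cohort(cohort_config(n = n, seed = seed))
  simulate_cohort_pairs(coh, seed = seed, ...)
}

test_that("paired simulation is deterministic and isolates the treatment effect", {
  coh <- generate_cohort(cohort_config(n = 1, seed = 21))
  a <- simulate_patient_pair(coh, seed = 3)
  b <- simulate_patient_pair(coh, seed = 3)
  expect_identical(a$treated, b$treated)
  expect_identical(a$untreated, b$untreated)

  null_pair <- simulate_patient_pair(
    coh, progression = progression_params(treatment_effect = 0), seed = 3)
  expect_identical(null_pair$treated[setdiff(names(null_pair$treated), "on_treatment")],
                   null_pair$untreated[setdiff(names(null_pair$untreated), "on_treatment")])
})

test_that("scenario composition matches the perspective inclusion matrix", {
  pairs <- small_pairs()
  pp <- pairs$per_patient
  inclusion <- list(  # caregiver utility, caregiver HC, patient non-HC, caregiver productivity
    A = c(FALSE, FALSE, FALSE, FALSE),
    B = c(FALSE, TRUE, FALSE, FALSE),
    C = c(TRUE, TRUE, FALSE, FALSE),
    D = c(FALSE, FALSE, TRUE, FALSE),
    E = c(FALSE, TRUE, TRUE, TRUE),
    F = c(TRUE, TRUE, TRUE, TRUE))
  for (id in names(inclusion)) {
    sc <- builtin_scenarios()[[id]]
    inc <- inclusion[[id]]
    expect_identical(c(sc$include_caregiver_utility, sc$include_caregiver_healthcare,
                       sc$include_patient_nonhealthcare, sc$include_caregiver_productivity),
                     inc, info = id)
    r <- evaluate_scenario(pairs, sc)
    expected_cost <- mean(pp$cost_drug_trt) + mean(pp$cost_patient_healthcare_trt) +
      inc[2] * mean(pp$cost_caregiver_healthcare_trt) +
      inc[3] * mean(pp$cost_patient_nonhealthcare_trt) +
      inc[4] * mean(pp$cost_caregiver_productivity_trt)
    expect_equal(r$cost_trt, expected_cost, tolerance = 1e-12, info = id)
    expected_q <- mean(pp$qaly_patient_trt) + inc[1] * mean(pp$qaly_caregiver_trt)
    expect_equal(r$qalys_trt, expected_q, tolerance = 1e-12, info = id)
    # comparator arm never accrues drug cost
    expect_equal(unname(r$cost_components_ctl["drug"]), 0)
  }
  # QALYs differ across scenarios only where caregiver utility is included
  res <- lapply(builtin_scenarios(), evaluate_scenario, pairs = pairs)
  expect_equal(res$A$incremental_qalys, res$B$incremental_qalys)
  expect_equal(res$A$incremental_qalys, res$D$incremental_qalys)
  expect_equal(res$C$incremental_qalys, res$F$incremental_qalys)
  expect_gt(res$C$incremental_qalys, res$A$incremental_qalys)
})

test_that("scenario evaluation is a bit-reproducible post-processing of stored pairs", {
  pairs <- small_pairs(n = 100, seed = 5)
  sc <- builtin_scenarios()$F
  expect_identical(evaluate_scenario(pairs, sc), evaluate_scenario(pairs, sc))
  expect_error(evaluate_scenario(pairs, scenario_spec("X", discount_rate = 0.05)),
               "discount rate")
})

test_that("one-time re-pricing changes only the drug component and is monotone in price", {
  pairs <- small_pairs(n = 300, seed = 13)
  sc <- builtin_scenarios()$A
  base <- evaluate_scenario(pairs, sc)
  ot1 <- evaluate_scenario(as_one_time(pairs, 100000), sc)
  ot2 <- evaluate_scenario(as_one_time(pairs, 250000), sc)
  expect_identical(ot1$incremental_qalys, base$incremental_qalys)
  expect_equal(ot1$incremental_cost - base$incremental_cost,
               100000 - base$incremental_cost_components[["drug"]],
               tolerance = 1e-6)
  expect_gt(ot2$icer, ot1$icer)
  # zero price: arms differ only through the treatment effect
  ot0 <- evaluate_scenario(as_one_time(pairs, 0), sc)
  expect_equal(unname(ot0$incremental_cost_components["drug"]), 0)
})

test_that("ICER dominance quadrants are labelled", {
  expect_equal(icer_value(35205, 0.193)$icer, 35205 / 0.193)
  expect_identical(icer_value(-10, 0.1)$label, "dominant")
  expect_identical(icer_value(10, -0.1)$label, "dominated")
  expect_identical(icer_value(10, 0)$label, "undefined")
})

test_that("the scenario suite runs every perspective on one shared pair set", {
  cfg <- run_config(n = 150, seed = 17)
  suite <- run_scenario_suite(cfg)
  expect_identical(suite$scenario_table$scenario, c("A", "B", "C", "D", "E", "F"))
  expect_identical(nrow(suite$onetime), 5L)  # repeated base + 2 prices x 2 scales
  expect_identical(suite$config_hash, config_hash(cfg))
  # re-running with the same config reproduces the tables exactly
  suite2 <- run_scenario_suite(cfg)
  expect_identical(suite$scenario_table, suite2$scenario_table)
  expect_identical(suite$onetime, suite2$onetime)
})
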