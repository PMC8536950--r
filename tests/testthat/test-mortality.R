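ref_baseline <- function(sex = "male", mmse0 = 27) {
  list(sex = sex, mmse0 = mmse0)
}

test_that("with null betas the cycle probability equals the life-table conversion", {
  params <- mortality_params(beta_mmse = 0, beta_decline = 0, beta_baseline_mmse = 0)
  st <- patient_state(age = 77, mmse = 12, cdrsb = 14, converted = TRUE,
                      decline_rate = 3)
  lt <- params$life_table
  q <- lt$annual_q[lt$sex == "male" & lt$age_lo == 75]
  expect_equal(mortality_probability(st, ref_baseline(), params),
               1 - (1 - q)^(1 / 12), tolerance = 1e-15)
})

test_that("the reference patient has hazard ratio one and hazards are monotone", {
  params <- mortality_params()
  ref <- patient_state(age = 77, mmse = 30, cdrsb = 0, decline_rate = 0)
  lt <- params$life_table
  q <- lt$annual_q[lt$sex == "male" & lt$age_lo == 75]
  expect_equal(mortality_probability(ref, ref_baseline(mmse0 = 30), params),
               1 - (1 - q)^(1 / 12), tolerance = 1e-15)
  # strictly increasing as cognition worsens, everything else fixed
  p <- vapply(seq(30, 0, by = -2), function(m) {
    mortality_probability(patient_state(age = 77, mmse = m, cdrsb = 10,
                                        converted = TRUE),
                          ref_baseline(), params)
  }, numeric(1))
  expect_true(all(diff(p) > 0))
  # faster decline never lowers the hazard
  p_dec <- vapply(seq(0, 4, by = 0.5), function(d) {
    mortality_probability(patient_state(age = 77, mmse = 20, cdrsb = 10,
                                        converted = TRUE, decline_rate = d),
                          ref_baseline(), params)
  }, numeric(1))
  expect_true(all(diff(p_dec) > 0))
  dead <- patient_state(age = 77, mmse = 20, cdrsb = 10, converted = TRUE)
  dead$alive <- FALSE
  expect_error(mortality_probability(dead, ref_baseline(), params), "dead")
})

test_that("institutionalization risk is monotone in time-in-stage and age, zero for MCI", {
  params <- institutionalization_params()
  st_at <- function(mis, age = 75, stage_mmse = 18) {
    patient_state(age = age, mmse = stage_mmse, cdrsb = 9, converted = TRUE,
                  months_in_stage = mis)
  }
  p <- vapply(seq(0, 60, by = 6), function(m)
    institutionalization_probability(st_at(m), ref_baseline(), params), numeric(1))
  expect_true(all(diff(p) >= 0))
  p_age <- vapply(c(65, 75, 85), function(a)
    institutionalization_probability(st_at(12, age = a), ref_baseline(), params),
    numeric(1))
  expect_true(all(diff(p_age) > 0))
  mci <- patient_state(age = 80, mmse = 27, cdrsb = 2)
  expect_equal(institutionalization_probability(mci, ref_baseline(), params), 0)
  # female multiplier
  st <- st_at(12)
  expect_equal(institutionalization_probability(st, ref_baseline("female"), params) /
                 institutionalization_probability(st, ref_baseline("male"), params),
               1.1, tolerance = 1e-12)
  res <- st_at(12); res$location <- "residential"
  expect_error(institutionalization_probability(res, ref_baseline(), params),
               "residential")
})

test_that("death and residential care are absorbing along simulated trajectories", {
  for (seed in 1:4) {
    coh <- generate_cohort(cohort_config(n = 1, seed = seed + 40))
    pp <- simulate_patient_pair(coh, seed = seed)
    for (arm in list(pp$treated, pp$untreated)) {
      expect_true(all(diff(as.integer(!arm$alive)) >= 0))
      expect_true(all(diff(as.integer(arm$location == "residential")) >= 0))
      # a dead patient's state is frozen
      dead_rows <- which(!arm$alive)
      if (length(dead_rows) > 1) {
        frozen <- arm[dead_rows, c("mmse", "cdrsb", "npi", "stage", "location")]
        expect_true(all(vapply(frozen, function(col)
          length(unique(col)) == 1, logical(1))))
      }
    }
  }
})

test_that("with null adjustment the simulated survival matches the analytic life-table curve", {
  # homogeneous cohort, disease-independent mortality, undiscounted life-years
  n <- 10000
  coh <- homogeneous_cohort(n, seed = 7)
  params <- premise_world_params()
  pairs <- simulate_cohort_pairs(
    coh, mortality = params$mortality,
    institutionalization = params$institutionalization,
    discount_rate = 0, seed = 11)
  lt <- params$mortality$life_table
  age <- coh$age[1]
  T_max <- ceiling((105 - age) * 12)
  s <- 1; ly_expected <- 0
  for (t in seq_len(T_max)) {
    a <- age + t / 12
    sub <- lt[lt$sex == "male", ]; sub <- sub[order(sub$age_lo), ]
    q <- sub$annual_q[min(max(findInterval(a, sub$age_lo), 1), nrow(sub))]
    s <- s * (1 - q)^(1 / 12)
    ly_expected <- ly_expected + s / 12
  }
  ly <- pairs$per_patient$ly_ctl
  expect_lt(abs(mean(ly) - ly_expected), 3 * stats::sd(ly) / sqrt(n))
  # identical random streams and a disease-blind hazard: arms die together
  expect_identical(pairs$per_patient$ly_trt, pairs$per_patient$ly_ctl)
})

test_that("the bundled synthetic life-table fixture round-trips the in-code default", {
  path <- system.file("extdata", "life_table_synthetic.csv", package = "adcea")
  lt <- read_life_table(path)
  expect_equal(lt, default_life_table(), tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(age_lo = 55, age_hi = 60, sex = "male",
                              annual_q = 1.5), bad, row.names = FALSE)
  expect_error(read_life_table(bad), "annual_q")
})
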