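# Reusable simulation "worlds" for the tests.

# Degenerate cohort: every patient identical (needed by the deterministic
# cohort-Markov oracle, which propagates expectations over a single shared
# score trajectory).
homogeneous_cohort <- function(n, seed = 101, age = 73, mmse0 = 27) {
  w <- rep(0, 7); w[mmse0 - 23] <- 1
  generate_cohort(cohort_config(
    n = n, seed = seed, age_mean = age, age_sd = 0, age_bounds = c(age, age),
    prop_female = 0, mmse_weights = w, cdrsb_mean = 1.5, cdrsb_sd = 0,
    npi_mean = 3, npi_sd = 0, prop_with_caregiver = 1))
}

# A world in which treatment provably only shifts severity occupancy:
# mortality is disease-independent (all betas 0) and institutionalization is
# stage- and duration-independent, so under common random numbers death and
# institutionalization times are identical across arms and every cost/utility
# difference comes from the severity gradient alone.
premise_world_params <- function() {
  list(
    mortality = mortality_params(beta_mmse = 0, beta_decline = 0,
                                 beta_baseline_mmse = 0),
    institutionalization = institutionalization_params(
      base_monthly_rate_by_stage = c(MCI = 0.004, mild = 0.004,
                                     moderate = 0.004, severe = 0.004),
      gamma_time_in_stage = 0, gamma_age = 0.03, female_multiplier = 1.1))
}
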