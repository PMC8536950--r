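# Deterministic cohort-level oracle for a homogeneous cohort.
#
# With every patient identical, no random discontinuation and the
# severity-based stopping rule only, the score trajectory of each arm is a
# deterministic function of time, so the microsimulation's only randomness is
# in the institutionalization and death times. This oracle propagates the
# exact state-occupancy expectations (community / residential / dead) cycle
# by cycle with plain arithmetic, independent of the engine's internals, and
# returns expected discounted QALYs, life-years and cost components per
# patient. Microsimulation cohort means must agree within Monte-Carlo error.
oracle_arm <- function(baseline, treated,
                       progression = progression_params(annual_discontinuation = 0),
                       mortality = mortality_params(),
                       institutionalization = institutionalization_params(),
                       utilities = utility_model(),
                       costs = cost_table(),
                       annual_price = 16000,
                       discount_rate = 0.03, max_age = 105) {
  stopifnot(progression$annual_discontinuation == 0)
  age <- baseline$age
  sex <- as.character(baseline$sex)
  mmse <- as.numeric(baseline$mmse0); mmse0 <- mmse
  cdrsb <- baseline$cdrsb0; npi <- baseline$npi0
  cg_age <- baseline$caregiver_age
  stages <- c("MCI", "mild", "moderate", "severe")
  stage <- "MCI"; converted <- FALSE; mis <- 0; on_trt <- treated
  cdr_rate <- progression$annual_cdrsb_change_by_stage
  npi_rate <- progression$annual_npi_change_by_stage
  lt <- mortality$life_table
  norms <- utilities$population_norms[order(utilities$population_norms$age_lo), ]
  norm_at <- function(a) norms$utility[max(1, findInterval(a, norms$age_lo))]
  band_u <- function(m) {
    if (m >= 21) utilities$caregiver_dementia_utility[["b21_26"]]
    else if (m >= 15) utilities$caregiver_dementia_utility[["b15_20"]]
    else utilities$caregiver_dementia_utility[["b0_14"]]
  }
  q_base <- function(a) {
    sub <- lt[lt$sex == sex, ]; sub <- sub[order(sub$age_lo), ]
    i <- min(max(findInterval(a, sub$age_lo), 1), nrow(sub))
    sub$annual_q[i]
  }
  T_max <- max(1, ceiling((max_age - age) * 12))
  p_comm <- 1; p_res <- 0; p_dead <- 0
  q_pat <- 0; q_cg <- 0; ly <- 0
  cost <- c(drug = 0, patient_healthcare = 0, patient_nonhealthcare = 0,
            caregiver_healthcare = 0, caregiver_productivity = 0)
  mmse_hist <- numeric(T_max)
  for (t in seq_len(T_max)) {
    eff <- if (on_trt) 1 - progression$treatment_effect else 1
    d <- min(18 - cdrsb, cdr_rate[[stage]] / 12 * eff)
    cdrsb <- cdrsb + d
    mmse <- max(0, mmse - progression$mmse_per_cdrsb * d)
    npi <- max(0, npi + npi_rate[[stage]] / 12)
    if (cdrsb >= progression$conversion_cdrsb) converted <- TRUE
    new_stage <- if (!converted) "MCI" else if (mmse >= 21) "mild" else if (mmse >= 15) "moderate" else "severe"
    mis <- if (new_stage == stage) mis + 1 else 0
    stage <- new_stage
    age <- age + 1 / 12
    if (match(stage, stages) >= match(progression$stop_stage, stages)) on_trt <- FALSE
    p_inst <- min(1, institutionalization$base_monthly_rate_by_stage[[stage]] *
                    exp(institutionalization$gamma_time_in_stage * mis +
                          institutionalization$gamma_age * (age - 75)) *
                    (if (sex == "female") institutionalization$female_multiplier else 1))
    p_res <- p_res + p_comm * p_inst
    p_comm <- p_comm * (1 - p_inst)
    decline <- if (t > 12) (mmse_hist[t - 12] - mmse) else 0
    mmse_hist[t] <- mmse
    hr <- exp(mortality$beta_mmse * (30 - mmse) + mortality$beta_decline * decline +
                mortality$beta_baseline_mmse * (30 - mmse0))
    p_mort <- min(1, 1 - (1 - q_base(age))^(hr / 12))
    p_dead <- p_dead + (p_comm + p_res) * p_mort
    p_comm <- p_comm * (1 - p_mort)
    p_res <- p_res * (1 - p_mort)
    df <- (1 + discount_rate)^(-t / 12)
    clamp01 <- function(u) min(1, max(0, u))
    u_comm <- clamp01(utilities$intercept + utilities$coef_mmse * mmse +
                        utilities$coef_npi * npi + utilities$coef_lives_with_caregiver)
    u_res <- clamp01(utilities$intercept + utilities$coef_mmse * mmse +
                       utilities$coef_npi * npi + utilities$coef_institutionalized)
    q_pat <- q_pat + (p_comm * u_comm + p_res * u_res) * df / 12
    ly <- ly + (p_comm + p_res) * df / 12
    w_comm <- if (stage == "MCI") utilities$caregiver_mci_utility else band_u(mmse)
    q_cg <- q_cg + (p_comm * w_comm + (p_res + p_dead) * norm_at(cg_age + t / 12)) * df / 12
    cost["patient_healthcare"] <- cost["patient_healthcare"] +
      (p_comm + p_res) * costs$patient_healthcare[[stage]] * df
    cost["patient_nonhealthcare"] <- cost["patient_nonhealthcare"] +
      (p_comm + p_res) * costs$patient_nonhealthcare[[stage]] * df
    cost["caregiver_healthcare"] <- cost["caregiver_healthcare"] +
      p_comm * costs$caregiver_healthcare[[stage]] * df
    cost["caregiver_productivity"] <- cost["caregiver_productivity"] +
      p_comm * costs$caregiver_productivity[[stage]] * df
    if (treated && on_trt) {
      cost["drug"] <- cost["drug"] + (p_comm + p_res) * annual_price / 12 * df
    }
  }
  list(qaly_patient = q_pat, qaly_caregiver = q_cg, ly = ly, cost = cost)
}
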