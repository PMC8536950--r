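## Mortality: an age/sex life-table baseline adjusted by a proportional-hazard
## term in current cognition, the trailing annual MMSE decline rate, and
## baseline cognition. The bundled life table is a synthetic Gompertz-type
## schedule (a documented stand-in, overridable via read_life_table()).

#' A synthetic age/sex annual mortality table
#'
#' Five-year age bands from 55 to 105 with annual death probabilities
#' following a Gompertz-type schedule, `q = A_sex * exp(0.09 (age_mid - 60))`
#' with `A_female = 0.0055`, `A_male = 0.008`, capped at 0.7. This is a
#' synthetic stand-in for a national life table, bundled so the model runs
#' with no external data; replace it via [read_life_table()] for applied work.
#'
#' @return a data.frame with columns `age_lo`, `age_hi`, `sex`, `annual_q`.
#' @export
default_life_table <- function() {
  age_lo <- seq(55, 100, by = 5)
  mids <- age_lo + 2.5
  q <- function(A) pmin(0.7, A * exp(0.09 * (mids - 60)))
  rbind(
    data.frame(age_lo = age_lo, age_hi = age_lo + 5, sex = "female",
               annual_q = q(0.0055)),
    data.frame(age_lo = age_lo, age_hi = age_lo + 5, sex = "male",
               annual_q = q(0.0080)))
}

#' Read a life table from CSV
#'
#' Expected columns: `age_lo`, `age_hi`, `sex` (female/male), `annual_q` in
#' \[0, 1\]. Bands must tile ages without gaps per sex.
#'
#' @param path CSV file path.
#' @return a validated life-table data.frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(lt, origin = path)
}

validate_life_table <- function(lt, origin = "life_table") {
  need <- c("age_lo", "age_hi", "sex", "annual_q")
  missing_cols <- setdiff(need, names(lt))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", origin,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(lt$annual_q < 0 | lt$annual_q > 1)) {
    stop(sprintf("%s: annual_q must be in [0, 1]", origin), call. = FALSE)
  }
  if (!all(lt$sex %in% c("female", "male"))) {
    stop(sprintf("%s: sex must be female/male", origin), call. = FALSE)
  }
  lt
}

## Annual baseline q for given ages/sexes; ages beyond the last band use the
## last band's q (the simulation horizon caps age anyway).
.life_table_q <- function(lt, age, sex) {
  q <- numeric(length(age))
  for (s in c("female", "male")) {
    sel <- sex == s
    if (!any(sel)) next
    sub <- lt[lt$sex == s, , drop = FALSE]
    sub <- sub[order(sub$age_lo), , drop = FALSE]
    i <- findInterval(age[sel], sub$age_lo)
    i[i < 1] <- 1L
    i[i > nrow(sub)] <- nrow(sub)
    q[sel] <- sub$annual_q[i]
  }
  q
}

#' Mortality hazard parameters
#'
#' The per-cycle death probability is
#' `p = 1 - (1 - q_age_sex)^(HR * cycle_length/12)` with
#' `HR = exp(beta_mmse (30 - mmse) + beta_decline * declineRate +
#' beta_baseline_mmse (30 - mmse0))`, where `declineRate` is the trailing
#' 12-month MMSE loss (0 during the first simulated year). The beta defaults
#' are transparent placeholders standing in for an unpublished registry-based
#' hazard equation; the covariate set (age, sex, baseline MMSE, annual MMSE
#' decline rate) is the modelled one.
#'
#' @param life_table a life-table data.frame ([default_life_table()]).
#' @param beta_mmse log-hazard per point of (30 - current MMSE).
#' @param beta_decline log-hazard per (MMSE point/year) of decline.
#' @param beta_baseline_mmse log-hazard per point of (30 - baseline MMSE).
#' @return an object of class `ad_mortality_params`.
#' @export
mortality_params <- function(life_table = default_life_table(),
                             beta_mmse = 0.03, beta_decline = 0.05,
                             beta_baseline_mmse = 0.01) {
  life_table <- validate_life_table(life_table)
  for (nm in c("beta_mmse", "beta_decline", "beta_baseline_mmse")) {
    v <- get(nm)
    if (!is.finite(v)) {
      stop(sprintf("invalid mortality config: field '%s' must be finite", nm),
           call. = FALSE)
    }
  }
  structure(list(life_table = life_table, beta_mmse = beta_mmse,
                 beta_decline = beta_decline,
                 beta_baseline_mmse = beta_baseline_mmse),
            class = "ad_mortality_params")
}

.mortality_prob <- function(age, sex, mmse, mmse0, decline_rate, params,
                            cycle_length = 1) {
  q <- .life_table_q(params$life_table, age, sex)
  hr <- exp(params$beta_mmse * (MMSE_MAX - mmse) +
              params$beta_decline * decline_rate +
              params$beta_baseline_mmse * (MMSE_MAX - mmse0))
  pmin(1, pmax(0, 1 - (1 - q)^(hr * cycle_length / 12)))
}

#' Per-cycle death probability
#'
#' @param state an alive [patient_state()]; its `decline_rate` field carries
#'   the trailing 12-month MMSE loss.
#' @param baseline one baseline record (a row of an `ad_cohort`, or any list
#'   with `sex` and `mmse0`).
#' @param params [mortality_params()].
#' @param cycle_length months.
#' @return probability of death this cycle, in \[0, 1\].
#' @export
mortality_probability <- function(state, baseline, params = mortality_params(),
                                  cycle_length = 1) {
  stopifnot(inherits(state, "ad_patient_state"))
  if (!state$alive) stop("mortality_probability called on a dead patient", call. = FALSE)
  unname(.mortality_prob(state$age, as.character(baseline$sex), state$mmse,
                         baseline$mmse0, state$decline_rate, params, cycle_length))
}

#' Institutionalization hazard parameters
#'
#' Transition from community to residential care is driven by the time spent
#' at the current severity level, adjusted by current age and sex:
#' `rate = base_monthly_rate_by_stage[stage] * exp(gamma_time_in_stage *
#' months_in_stage + gamma_age * (age - 75)) * female_multiplier[if female]`,
#' clamped to \[0, 1\]. Residential care is absorbing.
#'
#' @param base_monthly_rate_by_stage named numeric per stage, monthly
#'   probabilities at the reference age 75 and zero months in stage.
#' @param gamma_time_in_stage log-rate slope per month in the current stage.
#' @param gamma_age log-rate slope per year of age over 75.
#' @param female_multiplier rate ratio for female patients.
#' @return an object of class `ad_institutionalization_params`.
#' @export
institutionalization_params <- function(base_monthly_rate_by_stage = c(
                                          MCI = 0, mild = 0.002,
                                          moderate = 0.008, severe = 0.02),
                                        gamma_time_in_stage = 0.01,
                                        gamma_age = 0.03,
                                        female_multiplier = 1.1) {
  b <- base_monthly_rate_by_stage
  if (!all(AD_STAGES %in% names(b))) {
    stop("invalid institutionalization config: field 'base_monthly_rate_by_stage' must name all four stages",
         call. = FALSE)
  }
  if (any(b < 0 | b > 1)) {
    stop("invalid institutionalization config: field 'base_monthly_rate_by_stage' must be in [0, 1]",
         call. = FALSE)
  }
  if (female_multiplier <= 0) {
    stop("invalid institutionalization config: field 'female_multiplier' must be > 0",
         call. = FALSE)
  }
  structure(list(base_monthly_rate_by_stage = b[AD_STAGES],
                 gamma_time_in_stage = gamma_time_in_stage,
                 gamma_age = gamma_age, female_multiplier = female_multiplier),
            class = "ad_institutionalization_params")
}

.inst_prob <- function(stage_idx, months_in_stage, age, sex, params,
                       cycle_length = 1) {
  rate <- params$base_monthly_rate_by_stage[stage_idx] * cycle_length *
    exp(params$gamma_time_in_stage * months_in_stage +
          params$gamma_age * (age - 75)) *
    ifelse(sex == "female", params$female_multiplier, 1)
  pmin(1, pmax(0, rate))
}

#' Per-cycle community-to-residential transition probability
#'
#' @param state an alive, community-dwelling [patient_state()].
#' @param baseline one baseline record with a `sex` field.
#' @param params [institutionalization_params()].
#' @param cycle_length months.
#' @return probability of institutionalization this cycle, in \[0, 1\].
#' @export
institutionalization_probability <- function(state, baseline,
                                             params = institutionalization_params(),
                                             cycle_length = 1) {
  stopifnot(inherits(state, "ad_patient_state"))
  if (!state$alive) {
    stop("institutionalization_probability called on a dead patient", call. = FALSE)
  }
  if (state$location != "community") {
    stop("institutionalization_probability called on a residential patient (residential care is absorbing)",
         call. = FALSE)
  }
  unname(.inst_prob(stage_index(state$stage), state$months_in_stage, state$age,
                    as.character(baseline$sex), params, cycle_length))
}
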