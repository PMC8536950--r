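## Disease progression: stage-specific constant annual change rates for
## CDR-SB and NPI, with MMSE driven by CDR-SB through a fixed linear coupling.
## The treatment effect is a proportional reduction of the CDR-SB change rate
## while on drug (and so reaches MMSE through the coupling); NPI is untreated.

#' Progression, treatment-effect and stopping-rule parameters
#'
#' The engine advances CDR-SB by a stage-specific constant annual rate,
#' couples MMSE to the applied CDR-SB increment (`mmse_per_cdrsb` MMSE points
#' lost per CDR-SB point gained), and advances NPI by its own stage-specific
#' rate, unaffected by treatment. While on drug the CDR-SB change rate is
#' multiplied by `1 - treatment_effect` (base case: a 25% reduction in the
#' CDR-SB change rate). Treatment stops permanently at `stop_stage` or on a
#' random discontinuation draw (10%/year base case), with no residual benefit.
#' MCI converts to dementia when CDR-SB first reaches `conversion_cdrsb`.
#'
#' @param cycle_length cycle length in months (default 1).
#' @param annual_cdrsb_change_by_stage named numeric, points/year for stages
#'   MCI, mild, moderate, severe; all >= 0.
#' @param annual_npi_change_by_stage named numeric, points/year per stage.
#' @param mmse_per_cdrsb MMSE points lost per CDR-SB point gained (>= 0).
#' @param treatment_effect proportional reduction of the CDR-SB change rate
#'   while on drug, in \[0, 1\].
#' @param annual_discontinuation annual treatment discontinuation probability,
#'   in \[0, 1).
#' @param stop_stage severity stage at which the drug is stopped (default
#'   `"moderate"`; stopping also applies to any stage at least as severe).
#' @param residual_benefit logical; retained for interface completeness, the
#'   base case (and only supported value) is `FALSE` -- no benefit after
#'   discontinuation.
#' @param conversion_cdrsb CDR-SB threshold at which MCI converts to dementia.
#' @return an object of class `ad_progression_params`.
#' @export
progression_params <- function(cycle_length = 1,
                               annual_cdrsb_change_by_stage = c(
                                 MCI = 1.0, mild = 1.6, moderate = 2.0, severe = 2.0),
                               annual_npi_change_by_stage = c(
                                 MCI = 0.5, mild = 1.5, moderate = 1.5, severe = 1.5),
                               mmse_per_cdrsb = 1.6,
                               treatment_effect = 0.25,
                               annual_discontinuation = 0.10,
                               stop_stage = "moderate",
                               residual_benefit = FALSE,
                               conversion_cdrsb = 4.5) {
  bad <- function(field, msg) {
    stop(sprintf("invalid progression config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (cycle_length <= 0) bad("cycle_length", "must be > 0")
  cdr <- annual_cdrsb_change_by_stage
  npi <- annual_npi_change_by_stage
  if (!all(AD_STAGES %in% names(cdr))) {
    bad("annual_cdrsb_change_by_stage", "must name all four stages")
  }
  if (!all(AD_STAGES %in% names(npi))) {
    bad("annual_npi_change_by_stage", "must name all four stages")
  }
  if (any(cdr < 0)) bad("annual_cdrsb_change_by_stage", "must be >= 0 (disease worsens on average)")
  if (mmse_per_cdrsb < 0) bad("mmse_per_cdrsb", "must be >= 0")
  if (treatment_effect < 0 || treatment_effect > 1) bad("treatment_effect", "must be in [0, 1]")
  if (annual_discontinuation < 0 || annual_discontinuation >= 1) {
    bad("annual_discontinuation", "must be in [0, 1)")
  }
  stop_stage <- match.arg(stop_stage, AD_STAGES)
  if (isTRUE(residual_benefit)) {
    bad("residual_benefit", "must be FALSE (no residual benefit is modelled)")
  }
  if (conversion_cdrsb < 0 || conversion_cdrsb > CDRSB_MAX) {
    bad("conversion_cdrsb", "must be in [0, 18]")
  }
  structure(
    list(cycle_length = cycle_length,
         annual_cdrsb_change_by_stage = cdr[AD_STAGES],
         annual_npi_change_by_stage = npi[AD_STAGES],
         mmse_per_cdrsb = mmse_per_cdrsb,
         treatment_effect = treatment_effect,
         annual_discontinuation = annual_discontinuation,
         stop_stage = stop_stage,
         residual_benefit = FALSE,
         conversion_cdrsb = conversion_cdrsb),
    class = "ad_progression_params")
}

## Vectorised progression kernel. Returns the updated continuous scores and
## conversion flag; severity restaging and months_in_stage are handled by the
## caller so the in-cycle event ordering stays in one place.
.progress_scores <- function(cdrsb, mmse, npi, stage_idx, converted, on_drug, params) {
  frac <- params$cycle_length / 12
  eff <- ifelse(on_drug, 1 - params$treatment_effect, 1)
  d_raw <- params$annual_cdrsb_change_by_stage[stage_idx] * frac * eff
  new_cdrsb <- pmin(CDRSB_MAX, cdrsb + d_raw)
  d_app <- new_cdrsb - cdrsb
  new_mmse <- pmax(0, mmse - params$mmse_per_cdrsb * d_app)
  new_npi <- pmax(0, npi + params$annual_npi_change_by_stage[stage_idx] * frac)
  list(cdrsb = new_cdrsb, mmse = new_mmse, npi = new_npi,
       converted = converted | (new_cdrsb >= params$conversion_cdrsb))
}

#' Advance one patient by one progression cycle
#'
#' Applies the stage-specific CDR-SB change (reduced by the treatment effect
#' if `on_drug`), the MMSE coupling, and the NPI change; clamps all scores to
#' their scale bounds; re-stages severity; and increments (or resets, on a
#' stage change) the time-in-stage clock.
#'
#' @param state an alive [patient_state()].
#' @param params [progression_params()].
#' @param on_drug logical; is the treatment effect active this cycle?
#' @return the updated `ad_patient_state` (cycle index advanced by 1).
#' @export
step_progression <- function(state, params = progression_params(),
                             on_drug = state$on_treatment) {
  stopifnot(inherits(state, "ad_patient_state"))
  if (!state$alive) stop("step_progression called on a dead patient", call. = FALSE)
  s <- .progress_scores(state$cdrsb, state$mmse, state$npi,
                        stage_index(state$stage), state$converted, on_drug, params)
  new_stage_idx <- .sev_assign(s$converted, s$mmse)
  old_stage_idx <- stage_index(state$stage)
  state$cdrsb <- unname(s$cdrsb)
  state$mmse <- unname(s$mmse)
  state$npi <- unname(s$npi)
  state$converted <- unname(s$converted)
  state$months_in_stage <- if (new_stage_idx == old_stage_idx) {
    state$months_in_stage + params$cycle_length
  } else 0
  state$stage <- AD_STAGES[new_stage_idx]
  state$age <- state$age + params$cycle_length / 12
  state$cycle <- state$cycle + 1L
  state
}

#' Per-cycle treatment discontinuation
#'
#' Converts the annual discontinuation probability to a per-cycle probability
#' `p_cycle = 1 - (1 - annual)^(cycle_length/12)` (so that compounding over a
#' year recovers the annual rate exactly) and compares it to a uniform draw.
#'
#' @param params [progression_params()].
#' @param rng_draw a uniform draw in \[0, 1).
#' @return `TRUE` if the patient discontinues this cycle.
#' @export
sample_discontinuation <- function(params, rng_draw) {
  rng_draw < discontinuation_p_cycle(params)
}

#' @rdname sample_discontinuation
#' @export
discontinuation_p_cycle <- function(params) {
  1 - (1 - params$annual_discontinuation)^(params$cycle_length / 12)
}

#' Severity-based treatment stopping rule
#'
#' The drug is discontinued permanently once a patient develops moderate
#' dementia (or any stage at least as severe as `params$stop_stage`);
#' treatment never restarts.
#'
#' @param state a [patient_state()].
#' @param params [progression_params()].
#' @return the state, with `on_treatment` forced to `FALSE` if at or beyond
#'   the stopping stage. Idempotent.
#' @export
apply_stopping_rule <- function(state, params = progression_params()) {
  stopifnot(inherits(state, "ad_patient_state"))
  if (stage_index(state$stage) >= stage_index(params$stop_stage)) {
    state$on_treatment <- FALSE
  }
  state
}
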