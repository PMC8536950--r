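## Monthly cost components by severity stage (2021-era US $, held constant),
## drug pricing (annually repeated or one-time), and discounted accrual.

COST_COMPONENTS <- c("drug", "patient_healthcare", "patient_nonhealthcare",
                     "caregiver_healthcare", "caregiver_productivity")

#' Stage-specific monthly cost table
#'
#' Monthly US-dollar costs by severity stage for the four non-drug
#' components: patient health care, patient non-health care, caregiver health
#' care, and caregiver productivity (opportunity-cost valued, embedded in the
#' figures). Patient health care and caregiver productivity must be strictly
#' increasing with severity.
#'
#' @param patient_healthcare,patient_nonhealthcare,caregiver_healthcare,caregiver_productivity
#'   named numeric vectors over stages `MCI, mild, moderate, severe` ($/month,
#'   all >= 0).
#' @return an object of class `ad_cost_table`.
#' @export
cost_table <- function(patient_healthcare = c(MCI = 1174, mild = 1377,
                                              moderate = 1833, severe = 2105),
                       patient_nonhealthcare = c(MCI = 207, mild = 384,
                                                 moderate = 611, severe = 1025),
                       caregiver_healthcare = c(MCI = 705, mild = 731,
                                                moderate = 748, severe = 759),
                       caregiver_productivity = c(MCI = 925, mild = 2044,
                                                  moderate = 3019, severe = 5055)) {
  comps <- list(patient_healthcare = patient_healthcare,
                patient_nonhealthcare = patient_nonhealthcare,
                caregiver_healthcare = caregiver_healthcare,
                caregiver_productivity = caregiver_productivity)
  for (nm in names(comps)) {
    v <- comps[[nm]]
    if (!all(AD_STAGES %in% names(v))) {
      stop(sprintf("invalid cost config: field '%s' must name all four stages", nm),
           call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("invalid cost config: field '%s' must be >= 0", nm), call. = FALSE)
    }
    comps[[nm]] <- v[AD_STAGES]
  }
  for (nm in c("patient_healthcare", "caregiver_productivity")) {
    if (any(diff(comps[[nm]]) <= 0)) {
      stop(sprintf("invalid cost config: field '%s' must be strictly increasing with severity", nm),
           call. = FALSE)
    }
  }
  structure(comps, class = "ad_cost_table")
}

#' Drug pricing rule
#'
#' Either an annually repeated price accrued per cycle while on treatment
#' (base case $16,000/year), or a one-time price charged in full at treatment
#' initiation (cycle 0) in the treatment arm. `effect_scale` scales the
#' base-case treatment effect for pricing scenarios (e.g. 2 turns a 25%
#' CDR-SB slope reduction into 50%).
#'
#' @param mode `"repeated"` or `"one_time"`.
#' @param annual_price $/year while on treatment (repeated mode).
#' @param one_time_price $ charged once at cycle 0 (one-time mode).
#' @param effect_scale multiplier on the base-case treatment effect (>= 0).
#' @return an object of class `ad_drug_pricing`.
#' @export
drug_pricing <- function(mode = c("repeated", "one_time"), annual_price = 16000,
                         one_time_price = 100000, effect_scale = 1.0) {
  mode <- match.arg(mode)
  if (annual_price < 0) stop("invalid pricing config: field 'annual_price' must be >= 0", call. = FALSE)
  if (one_time_price < 0) stop("invalid pricing config: field 'one_time_price' must be >= 0", call. = FALSE)
  if (effect_scale < 0) stop("invalid pricing config: field 'effect_scale' must be >= 0", call. = FALSE)
  structure(list(mode = mode, annual_price = annual_price,
                 one_time_price = one_time_price, effect_scale = effect_scale),
            class = "ad_drug_pricing")
}

cost_breakdown <- function(drug = 0, patient_healthcare = 0,
                           patient_nonhealthcare = 0, caregiver_healthcare = 0,
                           caregiver_productivity = 0) {
  x <- c(drug = drug, patient_healthcare = patient_healthcare,
         patient_nonhealthcare = patient_nonhealthcare,
         caregiver_healthcare = caregiver_healthcare,
         caregiver_productivity = caregiver_productivity)
  structure(list(components = x, total = sum(x)), class = "ad_cost_breakdown")
}

#' Undiscounted cost increment for one cycle
#'
#' Each non-drug component is the stage's monthly value times the cycle
#' length. Caregiver components (health care and productivity) are 0 once the
#' patient is in residential care, mirroring the caregiver utility reset;
#' patient components continue. The drug component accrues
#' `annual_price * cycle_length/12` while on treatment in repeated mode, and
#' is never accrued per cycle in one-time mode (see [one_time_charge()]).
#'
#' @param state an alive [patient_state()].
#' @param table a [cost_table()].
#' @param pricing a [drug_pricing()].
#' @param cycle_length months.
#' @return an `ad_cost_breakdown`: `$components` (named numeric) and `$total`.
#' @export
cycle_costs <- function(state, table = cost_table(), pricing = drug_pricing(),
                        cycle_length = 1) {
  stopifnot(inherits(state, "ad_patient_state"))
  if (!state$alive) stop("cycle_costs called on a dead patient", call. = FALSE)
  i <- stage_index(state$stage)
  residential <- state$location == "residential"
  drug <- if (state$on_treatment && pricing$mode == "repeated") {
    pricing$annual_price * cycle_length / 12
  } else 0
  cost_breakdown(
    drug = drug,
    patient_healthcare = unname(table$patient_healthcare[i]) * cycle_length,
    patient_nonhealthcare = unname(table$patient_nonhealthcare[i]) * cycle_length,
    caregiver_healthcare = if (residential) 0 else unname(table$caregiver_healthcare[i]) * cycle_length,
    caregiver_productivity = if (residential) 0 else unname(table$caregiver_productivity[i]) * cycle_length)
}

#' One-time drug charge at treatment initiation
#'
#' The full one-time price is charged at cycle 0 (discount factor exactly 1)
#' in the treatment arm only; no per-cycle drug cost accrues thereafter.
#'
#' @param pricing a [drug_pricing()] with `mode = "one_time"`.
#' @return the charge in $.
#' @export
one_time_charge <- function(pricing) {
  if (pricing$mode != "one_time") {
    stop("one_time_charge called with pricing mode '", pricing$mode,
         "' (requires one_time)", call. = FALSE)
  }
  pricing$one_time_price
}

#' Discounted cost accrual over a stream of per-cycle breakdowns
#'
#' Component-wise `sum_t increment_t * (1 + rate)^(-t * cycle_length/12)`.
#'
#' @param increments a list of `ad_cost_breakdown` objects, or a data.frame
#'   with one column per component.
#' @param cycles cycle indices (defaults to `1:length(increments)`; cycle 0 is
#'   valid and discounts by exactly 1).
#' @param discount_rate annual discount rate (>= 0).
#' @param cycle_length months per cycle.
#' @return an `ad_cost_breakdown` of discounted totals.
#' @export
accrue_costs <- function(increments, cycles = NULL, discount_rate = 0.03,
                         cycle_length = 1) {
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  if (inherits(increments, "ad_cost_breakdown")) increments <- list(increments)
  if (is.list(increments) && !is.data.frame(increments)) {
    mat <- t(vapply(increments, function(b) b$components,
                    numeric(length(COST_COMPONENTS))))
  } else {
    mat <- as.matrix(increments[COST_COMPONENTS])
  }
  if (is.null(cycles)) cycles <- seq_len(nrow(mat))
  frac <- cycle_length / 12
  df <- (1 + discount_rate)^(-cycles * frac)
  tot <- as.numeric(crossprod(mat, df))
  names(tot) <- COST_COMPONENTS
  do.call(cost_breakdown, as.list(tot))
}

#' @export
print.ad_cost_breakdown <- function(x, ...) {
  cat("<cost breakdown> ($)\n")
  for (nm in names(x$components)) {
    cat(sprintf("  %-24s %12.2f\n", nm, x$components[[nm]]))
  }
  cat(sprintf("  %-24s %12.2f\n", "total", x$total))
  invisible(x)
}
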