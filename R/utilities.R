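## Health-state utilities. Patient utility is an additive EQ-5D-style
## regression in cognition, behaviour, institutionalization and living
## arrangement; caregiver utility is a per-patient scalar by the patient's
## severity/MMSE band, resetting to an age-specific population norm when the
## patient is institutionalized (or dies).

#' Age-band population-norm utilities
#'
#' Used for the caregiver utility reset at patient institutionalization or
#' death. Default schedule: 0.87 below age 65, 0.84 for 65-74, 0.80 at 75+.
#' These are plausible general-population EQ-5D norms, bundled as overridable
#' defaults.
#'
#' @return a data.frame with columns `age_lo`, `utility` (bands are
#'   `[age_lo, next age_lo)`; the first band extends downward).
#' @export
default_population_norms <- function() {
  data.frame(age_lo = c(0, 65, 75), utility = c(0.87, 0.84, 0.80))
}

#' Patient and caregiver utility model
#'
#' Patient utility (EQ-5D-style additive regression):
#' `u = 0.408 + 0.010 * MMSE - 0.04 * NPI - 0.159 * [institutionalized]
#'  + 0.051 * [lives with caregiver]`, clamped to \[0, 1\].
#' Caregiver utility: 1.00 while the patient has MCI; in dementia 0.85 /
#' 0.84 / 0.82 for patient MMSE bands 21-26 (and above), 15-20, 0-14; the
#' age-specific population norm once the patient is institutionalized or dead.
#'
#' @param intercept,coef_mmse,coef_npi,coef_institutionalized,coef_lives_with_caregiver
#'   regression coefficients of the patient utility equation.
#' @param caregiver_mci_utility caregiver utility while the patient has MCI.
#' @param caregiver_dementia_utility named numeric for patient-MMSE bands
#'   `b21_26`, `b15_20`, `b0_14`; must be strictly decreasing with worsening
#'   band.
#' @param population_norms data.frame as [default_population_norms()].
#' @return an object of class `ad_utility_model`.
#' @export
utility_model <- function(intercept = 0.408, coef_mmse = 0.010,
                          coef_npi = -0.04, coef_institutionalized = -0.159,
                          coef_lives_with_caregiver = 0.051,
                          caregiver_mci_utility = 1.00,
                          caregiver_dementia_utility = c(
                            b21_26 = 0.85, b15_20 = 0.84, b0_14 = 0.82),
                          population_norms = default_population_norms()) {
  cg <- caregiver_dementia_utility
  need <- c("b21_26", "b15_20", "b0_14")
  if (!all(need %in% names(cg))) {
    stop("invalid utility config: field 'caregiver_dementia_utility' must name bands ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  cg <- cg[need]
  if (!(cg["b21_26"] > cg["b15_20"] && cg["b15_20"] > cg["b0_14"])) {
    stop("invalid utility config: field 'caregiver_dementia_utility' must be strictly decreasing with worsening band",
         call. = FALSE)
  }
  if (!all(c("age_lo", "utility") %in% names(population_norms))) {
    stop("invalid utility config: field 'population_norms' must have columns age_lo, utility",
         call. = FALSE)
  }
  if (any(population_norms$utility < 0 | population_norms$utility > 1)) {
    stop("invalid utility config: field 'population_norms' utilities must be in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(intercept = intercept, coef_mmse = coef_mmse, coef_npi = coef_npi,
         coef_institutionalized = coef_institutionalized,
         coef_lives_with_caregiver = coef_lives_with_caregiver,
         caregiver_mci_utility = caregiver_mci_utility,
         caregiver_dementia_utility = cg,
         population_norms = population_norms[order(population_norms$age_lo), ]),
    class = "ad_utility_model")
}

.patient_utility <- function(mmse, npi, residential, lives_with_caregiver, model) {
  u <- model$intercept + model$coef_mmse * mmse + model$coef_npi * npi +
    model$coef_institutionalized * residential +
    model$coef_lives_with_caregiver * lives_with_caregiver
  pmin(1, pmax(0, u))
}

.population_norm <- function(age, model) {
  norms <- model$population_norms
  i <- findInterval(age, norms$age_lo)
  i[i < 1] <- 1L
  norms$utility[i]
}

## Caregiver utility kernel over vectors: patient dead or residential -> norm;
## MCI -> mci utility; dementia -> band by patient MMSE.
.caregiver_utility <- function(alive, residential, stage_idx, mmse,
                               caregiver_age, model) {
  band <- ifelse(mmse >= 21, model$caregiver_dementia_utility[["b21_26"]],
                 ifelse(mmse >= 15, model$caregiver_dementia_utility[["b15_20"]],
                        model$caregiver_dementia_utility[["b0_14"]]))
  u <- ifelse(stage_idx == 1L, model$caregiver_mci_utility, band)
  reset <- !alive | residential
  u[reset] <- .population_norm(caregiver_age[reset], model)
  pmin(1, pmax(0, u))
}

#' Patient utility weight for one cycle
#'
#' @param state an alive [patient_state()].
#' @param model a [utility_model()].
#' @param has_caregiver logical; does the patient live with a caregiver
#'   (applies only in the community)?
#' @return a utility weight in \[0, 1\].
#' @examples
#' st <- patient_state(age = 73, mmse = 30, cdrsb = 0.5, npi = 0)
#' patient_utility(st, utility_model())  # 0.408 + 0.300 + 0.051 = 0.759
#' @export
patient_utility <- function(state, model = utility_model(), has_caregiver = TRUE) {
  stopifnot(inherits(state, "ad_patient_state"))
  if (!state$alive) {
    stop("patient_utility called on a dead patient (utility accrual stops at death)",
         call. = FALSE)
  }
  residential <- state$location == "residential"
  unname(.patient_utility(state$mmse, state$npi, residential,
                          !residential && has_caregiver, model))
}

#' Caregiver utility weight for one cycle
#'
#' Returns the age-specific population norm when the patient is
#' institutionalized or dead, 1.00 while the patient has MCI in the
#' community, and the patient-MMSE band value in community dementia.
#'
#' @param state the patient's [patient_state()].
#' @param caregiver_age caregiver age in years.
#' @param model a [utility_model()].
#' @return a utility weight in \[0, 1\].
#' @export
caregiver_utility <- function(state, caregiver_age, model = utility_model()) {
  stopifnot(inherits(state, "ad_patient_state"))
  unname(.caregiver_utility(state$alive, state$location == "residential",
                            stage_index(state$stage), state$mmse,
                            caregiver_age, model))
}

#' Discounted QALY accrual over a utility stream
#'
#' `QALY = sum_t w_t * (cycle_length/12) * (1 + rate)^(-t * cycle_length/12)`
#' where `t` is the cycle index of each weight (accrual at cycle end).
#'
#' @param weights utility weights in \[0, 1\], or a data.frame with columns
#'   `cycle` and `weight`.
#' @param cycles cycle indices (defaults to `1:length(weights)`).
#' @param discount_rate annual discount rate (>= 0; default 0.03).
#' @param cycle_length months per cycle.
#' @return discounted QALYs (scalar).
#' @examples
#' accrue_qalys(rep(1, 12), discount_rate = 0)  # one undiscounted year
#' @export
accrue_qalys <- function(weights, cycles = NULL, discount_rate = 0.03,
                         cycle_length = 1) {
  if (is.data.frame(weights)) {
    cycles <- weights$cycle
    weights <- weights$weight
  }
  if (is.null(cycles)) cycles <- seq_along(weights)
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  if (!length(weights)) return(0)
  if (any(weights < 0 | weights > 1)) stop("weights must be in [0, 1]", call. = FALSE)
  frac <- cycle_length / 12
  sum(weights * frac * (1 + discount_rate)^(-cycles * frac))
}
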