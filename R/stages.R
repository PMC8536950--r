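#' @keywords internal
"_PACKAGE"

## Disease severity stages, ordered from least to most severe. Severity is
## staged solely on cognition (MMSE) once a patient has converted to dementia:
## mild >= 21, moderate 15-20, severe <= 14. Pre-conversion patients are MCI
## regardless of MMSE.
AD_STAGES <- c("MCI", "mild", "moderate", "severe")

MMSE_MAX <- 30
CDRSB_MAX <- 18

stage_index <- function(stage) {
  i <- match(stage, AD_STAGES)
  if (anyNA(i)) {
    stop("unknown severity stage: ", paste(unique(stage[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  i
}

## Vectorised severity kernel: integer stage index from conversion flag + MMSE.
.sev_assign <- function(converted, mmse) {
  if (any(mmse < 0 | mmse > MMSE_MAX)) {
    stop("mmse out of range [0, 30] in severity assignment", call. = FALSE)
  }
  idx <- ifelse(mmse >= 21, 2L, ifelse(mmse >= 15, 3L, 4L))
  ifelse(converted, idx, 1L)
}

#' Assign a disease severity stage from cognition
#'
#' Severity is defined solely on the MMSE once a patient has converted to
#' dementia: `mild` for MMSE >= 21, `moderate` for MMSE 15-20, `severe` for
#' MMSE <= 14. A patient who has not converted is staged `MCI` regardless of
#' MMSE.
#'
#' @param state a [patient_state()] (its `mmse` field is used), or a bare
#'   numeric MMSE value.
#' @param converted_to_dementia logical; has the patient converted from MCI to
#'   dementia? Defaults to the state's own `converted` flag when a state is
#'   given.
#' @return one of `"MCI"`, `"mild"`, `"moderate"`, `"severe"`.
#' @examples
#' assign_severity(18, converted_to_dementia = TRUE)   # "moderate"
#' assign_severity(26, converted_to_dementia = FALSE)  # "MCI"
#' @export
assign_severity <- function(state, converted_to_dementia = NULL) {
  if (inherits(state, "ad_patient_state")) {
    mmse <- state$mmse
    if (is.null(converted_to_dementia)) converted_to_dementia <- state$converted
  } else {
    mmse <- state
    if (is.null(converted_to_dementia)) {
      stop("converted_to_dementia must be given when passing a bare MMSE value",
           call. = FALSE)
    }
  }
  AD_STAGES[.sev_assign(converted_to_dementia, mmse)]
}

#' Construct a patient state record
#'
#' The time-evolving record of one simulated patient: cycle index, age,
#' clinical scale scores, severity stage, care location, vital status,
#' treatment flag and time spent in the current stage.
#'
#' @param age years.
#' @param mmse Mini-Mental State Examination score, 0-30 (higher = better).
#' @param cdrsb CDR Sum-of-Boxes score, 0-18 (higher = worse).
#' @param npi Neuropsychiatric Inventory score, >= 0.
#' @param stage severity stage; derived from `converted` and `mmse` if missing.
#' @param converted logical; has the patient converted from MCI to dementia?
#'   Defaults to `stage != "MCI"` when `stage` is supplied, else `FALSE`.
#' @param location `"community"` or `"residential"`.
#' @param alive logical.
#' @param on_treatment logical.
#' @param months_in_stage months spent in the current severity stage.
#' @param cycle integer cycle index (months since entry).
#' @param decline_rate trailing 12-month MMSE loss (points/year), used by the
#'   mortality hazard; 0 during the first simulated year.
#' @return an object of class `ad_patient_state`.
#' @export
patient_state <- function(age, mmse, cdrsb, npi = 0, stage = NULL,
                          converted = NULL, location = "community",
                          alive = TRUE, on_treatment = FALSE,
                          months_in_stage = 0, cycle = 0, decline_rate = 0) {
  if (mmse < 0 || mmse > MMSE_MAX) stop("mmse must be in [0, 30]", call. = FALSE)
  if (cdrsb < 0 || cdrsb > CDRSB_MAX) stop("cdrsb must be in [0, 18]", call. = FALSE)
  if (npi < 0) stop("npi must be >= 0", call. = FALSE)
  location <- match.arg(location, c("community", "residential"))
  if (is.null(converted)) converted <- if (is.null(stage)) FALSE else stage != "MCI"
  if (is.null(stage)) stage <- AD_STAGES[.sev_assign(converted, mmse)]
  stage <- match.arg(stage, AD_STAGES)
  structure(
    list(cycle = as.integer(cycle), age = age, mmse = mmse, cdrsb = cdrsb,
         npi = npi, stage = stage, converted = converted, location = location,
         alive = alive, on_treatment = on_treatment,
         months_in_stage = months_in_stage, decline_rate = decline_rate),
    class = "ad_patient_state")
}

#' @export
print.ad_patient_state <- function(x, ...) {
  cat(sprintf(
    "<patient state> cycle %d | age %.1f | MMSE %.1f | CDR-SB %.2f | NPI %.1f\n",
    x$cycle, x$age, x$mmse, x$cdrsb, x$npi))
  cat(sprintf("  stage %s | %s | %s | %s | %.0f mo in stage\n",
              x$stage, x$location,
              if (x$alive) "alive" else "dead",
              if (x$on_treatment) "on treatment" else "off treatment",
              x$months_in_stage))
  invisible(x)
}
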