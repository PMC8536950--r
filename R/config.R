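## Run configuration: a validated bundle of every sub-model's parameters,
## serialisable to JSON (the canonical on-disk format; no YAML parser is
## available in the supported dependency set). Unknown keys are rejected with
## their full field path; every output embeds the config hash.

#' Full run configuration
#'
#' Bundles cohort, progression, mortality, institutionalization, utility,
#' cost, pricing and scenario settings with the global seed, cohort size,
#' discount rate and horizon. `n` overrides the cohort config's own `n` so a
#' single knob controls the simulated size.
#'
#' @param n number of simulated patients.
#' @param seed integer master seed (cohort generation and simulation streams
#'   are both derived from it deterministically).
#' @param max_age horizon: trajectories end at death or this age (years).
#' @param discount_rate annual discount rate for costs and QALYs (default 3%).
#' @param cohort [cohort_config()].
#' @param progression [progression_params()].
#' @param mortality [mortality_params()].
#' @param institutionalization [institutionalization_params()].
#' @param utilities [utility_model()].
#' @param costs [cost_table()].
#' @param pricing a list with `annual_price` ($/yr, repeated mode),
#'   `one_time_prices` (sweep, $), `effect_scales` (sweep multipliers on the
#'   base-case effect).
#' @param scenarios named list of [scenario_spec()]; default [builtin_scenarios()].
#' @return an object of class `ad_run_config`.
#' @export
run_config <- function(n = 10000L, seed = 20211022L, max_age = 105,
                       discount_rate = 0.03,
                       cohort = cohort_config(),
                       progression = progression_params(),
                       mortality = mortality_params(),
                       institutionalization = institutionalization_params(),
                       utilities = utility_model(),
                       costs = cost_table(),
                       pricing = list(annual_price = 16000,
                                      one_time_prices = c(100000, 250000),
                                      effect_scales = c(1, 2)),
                       scenarios = NULL) {
  if (n < 1 || n != round(n)) {
    stop("invalid run config: field 'n' must be an integer >= 1", call. = FALSE)
  }
  if (discount_rate < 0) {
    stop("invalid run config: field 'discount_rate' must be >= 0", call. = FALSE)
  }
  if (max_age <= 0) stop("invalid run config: field 'max_age' must be > 0", call. = FALSE)
  for (nm in c("annual_price", "one_time_prices", "effect_scales")) {
    if (is.null(pricing[[nm]])) {
      stop(sprintf("invalid run config: field 'pricing.%s' is required", nm), call. = FALSE)
    }
    if (any(pricing[[nm]] < 0)) {
      stop(sprintf("invalid run config: field 'pricing.%s' must be >= 0", nm), call. = FALSE)
    }
  }
  extra <- setdiff(names(pricing), c("annual_price", "one_time_prices", "effect_scales"))
  if (length(extra)) {
    stop("invalid run config: unknown field(s) pricing.",
         paste(extra, collapse = ", pricing."), call. = FALSE)
  }
  if (is.null(scenarios)) scenarios <- builtin_scenarios(discount_rate)
  cohort$n <- as.integer(n)
  cohort$seed <- as.integer(seed)
  structure(list(n = as.integer(n), seed = as.integer(seed), max_age = max_age,
                 discount_rate = discount_rate, cohort = cohort,
                 progression = progression, mortality = mortality,
                 institutionalization = institutionalization,
                 utilities = utilities, costs = costs, pricing = pricing,
                 scenarios = scenarios),
            class = "ad_run_config")
}

## Plain nested-list image of a config (for serialisation and merging).
config_as_list <- function(config) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    ## named atomic vectors (stage maps, band maps) must serialise as JSON
    ## objects, not bare arrays, or their names are lost
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  out <- strip(config)
  out$scenarios <- lapply(config$scenarios, function(s) unclass(s))
  out
}

merge_config_lists <- function(base, override, path = character()) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base)) {
      stop("invalid config: unknown field '", full, "'", call. = FALSE)
    }
    bv <- base[[key]]
    ov <- override[[key]]
    if (is.list(bv) && !is.data.frame(bv) && is.list(ov) && !is.data.frame(ov) &&
        !is.null(names(ov)) && key != "scenarios") {
      base[[key]] <- merge_config_lists(bv, ov, c(path, key))
    } else {
      base[[key]] <- ov
    }
  }
  base
}

as_stage_map <- function(x) {
  v <- unlist(x)
  stats::setNames(as.numeric(v), names(v))
}

## Rebuild a validated ad_run_config from a plain nested list (e.g. parsed
## JSON merged over defaults); every sub-constructor re-validates.
config_from_list <- function(lst) {
  coh <- lst$cohort
  cohort <- cohort_config(
    n = coh$n, seed = coh$seed, age_mean = coh$age_mean, age_sd = coh$age_sd,
    age_bounds = as.numeric(unlist(coh$age_bounds)),
    prop_female = coh$prop_female,
    mmse_weights = as.numeric(unlist(coh$mmse_weights)),
    cdrsb_mean = coh$cdrsb_mean, cdrsb_sd = coh$cdrsb_sd,
    cdrsb_bounds = as.numeric(unlist(coh$cdrsb_bounds)),
    npi_mean = coh$npi_mean, npi_sd = coh$npi_sd, npi_lower = coh$npi_lower,
    prop_with_caregiver = coh$prop_with_caregiver,
    caregiver_age_offset = coh$caregiver_age_offset)
  pr <- lst$progression
  progression <- progression_params(
    cycle_length = pr$cycle_length,
    annual_cdrsb_change_by_stage = as_stage_map(pr$annual_cdrsb_change_by_stage),
    annual_npi_change_by_stage = as_stage_map(pr$annual_npi_change_by_stage),
    mmse_per_cdrsb = pr$mmse_per_cdrsb,
    treatment_effect = pr$treatment_effect,
    annual_discontinuation = pr$annual_discontinuation,
    stop_stage = pr$stop_stage,
    residual_benefit = isTRUE(pr$residual_benefit),
    conversion_cdrsb = pr$conversion_cdrsb)
  mo <- lst$mortality
  mortality <- mortality_params(
    life_table = as.data.frame(mo$life_table),
    beta_mmse = mo$beta_mmse, beta_decline = mo$beta_decline,
    beta_baseline_mmse = mo$beta_baseline_mmse)
  ins <- lst$institutionalization
  institutionalization <- institutionalization_params(
    base_monthly_rate_by_stage = as_stage_map(ins$base_monthly_rate_by_stage),
    gamma_time_in_stage = ins$gamma_time_in_stage,
    gamma_age = ins$gamma_age,
    female_multiplier = ins$female_multiplier)
  ut <- lst$utilities
  utilities <- utility_model(
    intercept = ut$intercept, coef_mmse = ut$coef_mmse, coef_npi = ut$coef_npi,
    coef_institutionalized = ut$coef_institutionalized,
    coef_lives_with_caregiver = ut$coef_lives_with_caregiver,
    caregiver_mci_utility = ut$caregiver_mci_utility,
    caregiver_dementia_utility = as_stage_map(ut$caregiver_dementia_utility),
    population_norms = as.data.frame(ut$population_norms))
  co <- lst$costs
  costs <- cost_table(
    patient_healthcare = as_stage_map(co$patient_healthcare),
    patient_nonhealthcare = as_stage_map(co$patient_nonhealthcare),
    caregiver_healthcare = as_stage_map(co$caregiver_healthcare),
    caregiver_productivity = as_stage_map(co$caregiver_productivity))
  scenarios <- NULL
  if (!is.null(lst$scenarios)) {
    scenarios <- lapply(lst$scenarios, function(s) {
      scenario_spec(
        id = s$id,
        include_caregiver_utility = isTRUE(s$include_caregiver_utility),
        include_caregiver_healthcare = isTRUE(s$include_caregiver_healthcare),
        include_patient_nonhealthcare = isTRUE(s$include_patient_nonhealthcare),
        include_caregiver_productivity = isTRUE(s$include_caregiver_productivity),
        discount_rate = if (is.null(s$discount_rate)) lst$discount_rate else s$discount_rate)
    })
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "id")
  }
  run_config(n = lst$n, seed = lst$seed, max_age = lst$max_age,
             discount_rate = lst$discount_rate, cohort = cohort,
             progression = progression, mortality = mortality,
             institutionalization = institutionalization, utilities = utilities,
             costs = costs,
             pricing = list(
               annual_price = lst$pricing$annual_price,
               one_time_prices = as.numeric(unlist(lst$pricing$one_time_prices)),
               effect_scales = as.numeric(unlist(lst$pricing$effect_scales))),
             scenarios = scenarios)
}

#' Load a run configuration from JSON
#'
#' Reads a (possibly partial) JSON config, merges it over the package
#' defaults, rejects unknown keys with their full field path, and
#' re-validates every sub-model. An empty file (or `{}`) yields the full
#' default configuration.
#'
#' @param path JSON file path.
#' @return a validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else {
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  }
  base <- config_as_list(run_config())
  merged <- merge_config_lists(base, user)
  config_from_list(merged)
}

#' Write a run configuration to JSON
#'
#' @param config an [run_config()].
#' @param path output file path (or `stdout()` for a `show-config` style dump).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ad_run_config"))
  txt <- jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE,
                          digits = NA, pretty = TRUE, dataframe = "rows")
  if (inherits(path, "connection")) {
    writeLines(txt, path)
  } else {
    writeLines(txt, path)
    return(invisible(path))
  }
  invisible(NULL)
}

#' Hash of a run configuration
#'
#' md5 over the canonical JSON serialisation; embedded in every result object
#' so equal hash + seed implies identical outputs.
#'
#' @param config an [run_config()].
#' @return a 32-character hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "ad_run_config"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE,
                              digits = NA, dataframe = "rows"), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.ad_run_config <- function(x, ...) {
  cat(sprintf("<run config> n = %d, seed = %d, horizon to age %.0f, discount %.1f%%/yr\n",
              x$n, x$seed, x$max_age, 100 * x$discount_rate))
  cat(sprintf("  treatment: %.0f%% CDR-SB slope reduction, %.0f%%/yr discontinuation, stop at %s dementia\n",
              100 * x$progression$treatment_effect,
              100 * x$progression$annual_discontinuation,
              x$progression$stop_stage))
  cat(sprintf("  drug: $%s/yr repeated; one-time sweep at $%s; effect scales %s\n",
              format(x$pricing$annual_price, big.mark = ","),
              paste(format(x$pricing$one_time_prices, big.mark = ",",
                           scientific = FALSE, trim = TRUE), collapse = ", $"),
              paste(x$pricing$effect_scales, collapse = ", ")))
  cat(sprintf("  scenarios: %s | config hash %s\n",
              paste(names(x$scenarios), collapse = ""), config_hash(x)))
  invisible(x)
}
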