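## Analytic perspectives (scenario matrix) and the ICER engine. Perspectives
## are evaluated by summing per-patient discounted aggregates from a single
## shared set of trajectory pairs; no re-simulation per scenario.

#' Define an analytic perspective (scenario)
#'
#' A scenario selects which utility and cost components enter the CEA.
#' Patient utility and patient health-care costs (including the drug) are
#' always included; caregiver utility, caregiver health-care costs, patient
#' non-health-care costs and caregiver productivity costs are switchable.
#'
#' @param id scenario label.
#' @param include_caregiver_utility,include_caregiver_healthcare,include_patient_nonhealthcare,include_caregiver_productivity
#'   logical switches.
#' @param discount_rate annual discount rate; must equal the rate the
#'   trajectory pairs were accrued at.
#' @return an object of class `ad_scenario_spec`.
#' @export
scenario_spec <- function(id,
                          include_caregiver_utility = FALSE,
                          include_caregiver_healthcare = FALSE,
                          include_patient_nonhealthcare = FALSE,
                          include_caregiver_productivity = FALSE,
                          discount_rate = 0.03) {
  if (discount_rate < 0) {
    stop("invalid scenario config: field 'discount_rate' must be >= 0", call. = FALSE)
  }
  structure(list(id = as.character(id),
                 include_patient_utility = TRUE,
                 include_patient_healthcare = TRUE,
                 include_caregiver_utility = isTRUE(include_caregiver_utility),
                 include_caregiver_healthcare = isTRUE(include_caregiver_healthcare),
                 include_patient_nonhealthcare = isTRUE(include_patient_nonhealthcare),
                 include_caregiver_productivity = isTRUE(include_caregiver_productivity),
                 discount_rate = discount_rate),
            class = "ad_scenario_spec")
}

#' The six built-in perspectives A-F
#'
#' A-C are health-care-sector perspectives, D-F societal:
#' A = patient utility + patient health care; B = A + caregiver health care;
#' C = B + caregiver utility; D = A + patient non-health care;
#' E = B + patient non-health care + caregiver productivity; F = everything.
#'
#' @param discount_rate annual discount rate shared by all six.
#' @return a named list of [scenario_spec()] objects.
#' @export
builtin_scenarios <- function(discount_rate = 0.03) {
  list(
    A = scenario_spec("A", discount_rate = discount_rate),
    B = scenario_spec("B", include_caregiver_healthcare = TRUE,
                      discount_rate = discount_rate),
    C = scenario_spec("C", include_caregiver_healthcare = TRUE,
                      include_caregiver_utility = TRUE,
                      discount_rate = discount_rate),
    D = scenario_spec("D", include_patient_nonhealthcare = TRUE,
                      discount_rate = discount_rate),
    E = scenario_spec("E", include_caregiver_healthcare = TRUE,
                      include_patient_nonhealthcare = TRUE,
                      include_caregiver_productivity = TRUE,
                      discount_rate = discount_rate),
    F = scenario_spec("F", include_caregiver_utility = TRUE,
                      include_caregiver_healthcare = TRUE,
                      include_patient_nonhealthcare = TRUE,
                      include_caregiver_productivity = TRUE,
                      discount_rate = discount_rate))
}

#' Compute an ICER from incremental cost and effect
#'
#' Returns the ratio when incremental QALYs are positive, and a dominance
#' label otherwise: `"dominant"` (cheaper and more effective), `"dominated"`
#' (costlier and less effective), `"undefined"` (zero QALY difference with a
#' non-zero cost difference).
#'
#' @param incremental_cost $.
#' @param incremental_qalys QALYs.
#' @return a list with `icer` (numeric or `NA`) and `label`.
#' @export
icer_value <- function(incremental_cost, incremental_qalys) {
  if (incremental_qalys > 0) {
    list(icer = incremental_cost / incremental_qalys,
         label = if (incremental_cost < 0) "dominant" else "icer")
  } else if (incremental_qalys < 0) {
    list(icer = NA_real_,
         label = if (incremental_cost > 0) "dominated" else "icer_sw_quadrant")
  } else {
    list(icer = NA_real_,
         label = if (incremental_cost == 0) "indifferent" else "undefined")
  }
}

#' Evaluate one perspective on stored trajectory pairs
#'
#' Cohort-mean discounted QALYs and costs per arm are formed by summing only
#' the scenario's included components (caregiver QALYs, when included, are
#' added directly to patient QALYs); the ICER follows from the incremental
#' values. Re-running on the same pairs is bit-reproducible.
#'
#' @param pairs an `ad_pair_set` from [simulate_cohort_pairs()].
#' @param scenario an [scenario_spec()].
#' @return an object of class `ad_cea_result` with per-arm means, incremental
#'   cost/QALYs/life-years with Monte-Carlo standard errors, the ICER (and
#'   dominance label), and the incremental cost component breakdown.
#' @export
evaluate_scenario <- function(pairs, scenario) {
  stopifnot(inherits(pairs, "ad_pair_set"), inherits(scenario, "ad_scenario_spec"))
  if (abs(scenario$discount_rate - pairs$discount_rate) > 1e-12) {
    stop(sprintf(
      "scenario '%s' discount rate (%.4f) differs from the rate the pairs were accrued at (%.4f); re-simulate",
      scenario$id, scenario$discount_rate, pairs$discount_rate), call. = FALSE)
  }
  pp <- pairs$per_patient
  n <- pairs$n
  qaly <- function(arm) {
    pp[[paste0("qaly_patient_", arm)]] +
      if (scenario$include_caregiver_utility) pp[[paste0("qaly_caregiver_", arm)]] else 0
  }
  cost_components <- function(arm) {
    comp <- c(drug = mean(pp[[paste0("cost_drug_", arm)]]),
              patient_healthcare = mean(pp[[paste0("cost_patient_healthcare_", arm)]]),
              patient_nonhealthcare = if (scenario$include_patient_nonhealthcare)
                mean(pp[[paste0("cost_patient_nonhealthcare_", arm)]]) else 0,
              caregiver_healthcare = if (scenario$include_caregiver_healthcare)
                mean(pp[[paste0("cost_caregiver_healthcare_", arm)]]) else 0,
              caregiver_productivity = if (scenario$include_caregiver_productivity)
                mean(pp[[paste0("cost_caregiver_productivity_", arm)]]) else 0)
    comp
  }
  cost_vec <- function(arm) {
    pp[[paste0("cost_drug_", arm)]] +
      pp[[paste0("cost_patient_healthcare_", arm)]] +
      (if (scenario$include_patient_nonhealthcare)
        pp[[paste0("cost_patient_nonhealthcare_", arm)]] else 0) +
      (if (scenario$include_caregiver_healthcare)
        pp[[paste0("cost_caregiver_healthcare_", arm)]] else 0) +
      (if (scenario$include_caregiver_productivity)
        pp[[paste0("cost_caregiver_productivity_", arm)]] else 0)
  }
  q_trt <- qaly("trt"); q_ctl <- qaly("ctl")
  c_trt <- cost_vec("trt"); c_ctl <- cost_vec("ctl")
  inc_q <- q_trt - q_ctl
  inc_c <- c_trt - c_ctl
  inc_ly <- pp$ly_trt - pp$ly_ctl
  incremental_cost <- mean(inc_c)
  incremental_qalys <- mean(inc_q)
  ic <- icer_value(incremental_cost, incremental_qalys)
  comp_trt <- cost_components("trt"); comp_ctl <- cost_components("ctl")
  structure(
    list(scenario = scenario$id,
         n = n, seed = pairs$seed,
         qalys_trt = mean(q_trt), qalys_ctl = mean(q_ctl),
         qalys_patient_trt = mean(pp$qaly_patient_trt),
         qalys_patient_ctl = mean(pp$qaly_patient_ctl),
         qalys_caregiver_trt = mean(pp$qaly_caregiver_trt),
         qalys_caregiver_ctl = mean(pp$qaly_caregiver_ctl),
         cost_trt = mean(c_trt), cost_ctl = mean(c_ctl),
         cost_components_trt = comp_trt, cost_components_ctl = comp_ctl,
         incremental_cost = incremental_cost,
         incremental_qalys = incremental_qalys,
         incremental_life_years = mean(inc_ly),
         incremental_cost_components = comp_trt - comp_ctl,
         se_incremental_cost = stats::sd(inc_c) / sqrt(n),
         se_incremental_qalys = stats::sd(inc_q) / sqrt(n),
         icer = ic$icer, icer_label = ic$label,
         pricing_mode = pairs$pricing$mode,
         effect_scale = pairs$pricing$effect_scale),
    class = "ad_cea_result")
}

#' @export
print.ad_cea_result <- function(x, ...) {
  cat(sprintf("<CEA result> scenario %s (n = %d, seed %d)\n", x$scenario, x$n, x$seed))
  cat(sprintf("  incremental cost:  %s (SE %s)\n",
              format_dollars(x$incremental_cost),
              format_dollars(x$se_incremental_cost)))
  cat(sprintf("  incremental QALYs: %.4f (SE %.4f)\n",
              x$incremental_qalys, x$se_incremental_qalys))
  if (x$icer_label %in% c("icer")) {
    cat(sprintf("  ICER: %s /QALY (%s rounded to nearest $1,000)\n",
                format_dollars(x$icer), format_dollars(round(x$icer / 1000) * 1000)))
  } else {
    cat(sprintf("  ICER: %s\n", x$icer_label))
  }
  invisible(x)
}

#' Run the full scenario suite
#'
#' Generates (or accepts) a cohort, simulates one shared set of
#' treated/untreated trajectory pairs with common random numbers, evaluates
#' the six built-in perspectives A-F on those pairs, and runs the one-time
#' pricing sweep (each configured effect scale re-simulated with the same
#' seed; each price is a re-pricing of those trajectories).
#'
#' @param config an [run_config()].
#' @param cohort optionally a pre-built `ad_cohort` (defaults to
#'   `generate_cohort(config$cohort)`).
#' @return an object of class `ad_cea_suite`: `$scenarios` (named list of
#'   `ad_cea_result` A-F), `$scenario_table` (data.frame), `$onetime`
#'   (data.frame of the pricing sweep incl. the repeated base case),
#'   `$pairs`, `$config_hash`, `$seed`.
#' @export
run_scenario_suite <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "ad_run_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  base_pricing <- drug_pricing(mode = "repeated",
                               annual_price = config$pricing$annual_price,
                               effect_scale = 1.0)
  sim <- function(pricing) {
    simulate_cohort_pairs(cohort,
                          progression = config$progression,
                          mortality = config$mortality,
                          institutionalization = config$institutionalization,
                          utilities = config$utilities,
                          costs = config$costs,
                          pricing = pricing,
                          discount_rate = config$discount_rate,
                          max_age = config$max_age,
                          seed = config$seed)
  }
  pairs <- sim(base_pricing)
  scenarios <- config$scenarios
  results <- lapply(scenarios, function(sc) evaluate_scenario(pairs, sc))
  scenario_table <- do.call(rbind, lapply(results, function(r) {
    data.frame(scenario = r$scenario,
               incremental_cost = r$incremental_cost,
               incremental_qalys = r$incremental_qalys,
               incremental_life_years = r$incremental_life_years,
               icer = r$icer, icer_label = r$icer_label)
  }))
  rownames(scenario_table) <- NULL

  ## One-time pricing sweep, evaluated under the base perspective (A)
  base_sc <- scenarios[["A"]]
  base_res <- results[["A"]]
  ot_rows <- list(data.frame(
    label = "repeated base case", mode = "repeated",
    effect_scale = 1, price = config$pricing$annual_price,
    incremental_cost = base_res$incremental_cost,
    incremental_qalys = base_res$incremental_qalys,
    icer = base_res$icer, icer_label = base_res$icer_label))
  for (es in config$pricing$effect_scales) {
    pairs_es <- if (es == 1) pairs else {
      sim(drug_pricing(mode = "repeated",
                       annual_price = config$pricing$annual_price,
                       effect_scale = es))
    }
    for (price in config$pricing$one_time_prices) {
      r <- evaluate_scenario(as_one_time(pairs_es, price), base_sc)
      eff_pct <- round(100 * pairs_es$treatment_effect)
      ot_rows[[length(ot_rows) + 1L]] <- data.frame(
        label = sprintf("one-time, %d%% effective, $%s", eff_pct,
                        format(price, big.mark = ",", scientific = FALSE)),
        mode = "one_time", effect_scale = es, price = price,
        incremental_cost = r$incremental_cost,
        incremental_qalys = r$incremental_qalys,
        icer = r$icer, icer_label = r$icer_label)
    }
  }
  onetime <- do.call(rbind, ot_rows)
  rownames(onetime) <- NULL
  structure(list(scenarios = results, scenario_table = scenario_table,
                 onetime = onetime, pairs = pairs,
                 seed = config$seed, n = nrow(cohort),
                 config_hash = config_hash(config)),
            class = "ad_cea_suite")
}

#' @export
print.ad_cea_suite <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
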