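## The microsimulation engine. Both arms (treated / untreated) advance in
## lockstep over monthly cycles, vectorised over patients, consuming identical
## per-cycle uniform draws per event type (common random numbers) so that arm
## differences isolate the treatment effect. In-cycle event order:
## progression -> severity restaging -> stopping rule -> discontinuation draw
## -> institutionalization draw -> mortality draw -> accrual.
##
## The engine stores per-patient *discounted aggregates* (QALYs, life-years,
## five cost components, severity occupancy) per arm; perspectives are a pure
## post-processing of these (see evaluate_scenario). Full per-cycle
## trajectories can be recorded for a single patient (record = TRUE).

new_arm <- function(cohort, on_treatment) {
  e <- new.env(parent = emptyenv())
  n <- nrow(cohort)
  e$cdrsb <- cohort$cdrsb0
  e$mmse <- as.numeric(cohort$mmse0)
  e$npi <- cohort$npi0
  e$age <- cohort$age
  e$converted <- rep(FALSE, n)
  e$stage_idx <- rep(1L, n)            # all enter as MCI (cdrsb0 < conversion)
  e$months_in_stage <- rep(0, n)
  e$residential <- rep(FALSE, n)
  e$alive <- rep(TRUE, n)
  e$on_treatment <- rep(on_treatment, n)
  e$q_pat <- numeric(n); e$q_cg <- numeric(n); e$ly <- numeric(n)
  e$c_drug <- numeric(n); e$c_phc <- numeric(n); e$c_pnhc <- numeric(n)
  e$c_chc <- numeric(n); e$c_cprod <- numeric(n)
  e$occ <- matrix(0, n, 4L)
  e
}

#' Simulate paired treated/untreated trajectories for a whole cohort
#'
#' Runs both arms of the microsimulation with common random numbers (one
#' uniform draw per patient, cycle and event type, shared across arms) and
#' returns per-patient discounted aggregates for each arm: patient QALYs,
#' caregiver QALYs, life-years, the five cost components, and discounted
#' severity-stage occupancy. Trajectories terminate at death or at
#' `max_age`. All accrual uses end-of-cycle states; patients accrue nothing
#' in or after the cycle of death, while caregivers of institutionalized or
#' deceased patients accrue the age-specific population-norm utility until
#' the patient's horizon.
#'
#' @param cohort an `ad_cohort` data.frame ([generate_cohort()]).
#' @param progression [progression_params()].
#' @param mortality [mortality_params()].
#' @param institutionalization [institutionalization_params()].
#' @param utilities [utility_model()].
#' @param costs [cost_table()].
#' @param pricing [drug_pricing()]; `effect_scale` multiplies the treatment
#'   effect, and in `one_time` mode the full price is charged at cycle 0 in
#'   the treatment arm with no per-cycle drug cost.
#' @param discount_rate annual discount rate applied to all accrual.
#' @param max_age simulation horizon in years of patient age.
#' @param seed integer seed for the simulation's random streams.
#' @param paired use common random numbers across arms (`TRUE`, the default)
#'   or independent streams per arm (for variance-reduction experiments).
#' @param record record full per-cycle trajectories (single-patient cohorts
#'   only; see [simulate_patient_pair()]).
#' @return an object of class `ad_pair_set`: `$per_patient` (one row per
#'   patient with `_trt` / `_ctl` aggregate columns), `$occupancy` (discounted
#'   person-years by stage and arm), and run metadata.
#' @export
simulate_cohort_pairs <- function(cohort,
                                  progression = progression_params(),
                                  mortality = mortality_params(),
                                  institutionalization = institutionalization_params(),
                                  utilities = utility_model(),
                                  costs = cost_table(),
                                  pricing = drug_pricing(),
                                  discount_rate = 0.03,
                                  max_age = 105,
                                  seed = 1L,
                                  paired = TRUE,
                                  record = FALSE) {
  validate_cohort_df(cohort)
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  n <- nrow(cohort)
  if (record && n != 1L) stop("record = TRUE requires a single-patient cohort", call. = FALSE)

  prog <- progression
  prog$treatment_effect <- min(1, progression$treatment_effect * pricing$effect_scale)
  cl <- prog$cycle_length
  frac <- cl / 12
  p_disc <- discontinuation_p_cycle(prog)
  stop_idx <- stage_index(prog$stop_stage)
  decline_window <- max(1L, as.integer(round(12 / cl)))

  sex <- as.character(cohort$sex)
  mmse0 <- as.numeric(cohort$mmse0)
  has_cg <- cohort$has_caregiver
  cg_age0 <- ifelse(has_cg, cohort$caregiver_age, 0)

  horizon <- pmax(1L, as.integer(ceiling((max_age - cohort$age) / frac)))
  t_max <- max(horizon)

  phc_m <- unname(costs$patient_healthcare)
  pnhc_m <- unname(costs$patient_nonhealthcare)
  chc_m <- unname(costs$caregiver_healthcare)
  cprod_m <- unname(costs$caregiver_productivity)
  drug_m <- if (pricing$mode == "repeated") pricing$annual_price * frac else 0

  old <- .Random.seed_exists()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  arms <- list(trt = new_arm(cohort, TRUE), ctl = new_arm(cohort, FALSE))
  hist_list <- list(trt = matrix(NA_real_, n, decline_window),
                    ctl = matrix(NA_real_, n, decline_window))
  rec <- if (record) {
    list(trt = vector("list", t_max), ctl = vector("list", t_max))
  } else NULL

  for (t in seq_len(t_max)) {
    if (paired) {
      u_disc <- stats::runif(n); u_inst <- stats::runif(n); u_mort <- stats::runif(n)
    }
    df_t <- (1 + discount_rate)^(-t * frac)
    slot <- ((t - 1L) %% decline_window) + 1L

    for (arm_name in c("trt", "ctl")) {
      a <- arms[[arm_name]]
      if (!paired) {
        u_disc <- stats::runif(n); u_inst <- stats::runif(n); u_mort <- stats::runif(n)
      }
      within_h <- t <= horizon
      idx <- which(a$alive & within_h)
      if (length(idx)) {
        on_drug <- if (arm_name == "trt") a$on_treatment[idx] else rep(FALSE, length(idx))
        s <- .progress_scores(a$cdrsb[idx], a$mmse[idx], a$npi[idx],
                              a$stage_idx[idx], a$converted[idx], on_drug, prog)
        a$cdrsb[idx] <- s$cdrsb
        a$mmse[idx] <- s$mmse
        a$npi[idx] <- s$npi
        a$converted[idx] <- s$converted
        a$age[idx] <- a$age[idx] + frac
        new_stage <- .sev_assign(s$converted, s$mmse)
        same <- new_stage == a$stage_idx[idx]
        a$months_in_stage[idx] <- ifelse(same, a$months_in_stage[idx] + cl, 0)
        a$stage_idx[idx] <- new_stage
        ## stopping rule, then random discontinuation (treatment arm only;
        ## the control arm never holds the drug)
        if (arm_name == "trt") {
          stop_now <- a$on_treatment[idx] & new_stage >= stop_idx
          a$on_treatment[idx][stop_now] <- FALSE
          disc <- a$on_treatment[idx] & (u_disc[idx] < p_disc)
          a$on_treatment[idx][disc] <- FALSE
        }
        ## institutionalization (community only; residential is absorbing)
        comm <- idx[!a$residential[idx]]
        if (length(comm)) {
          p_inst <- .inst_prob(a$stage_idx[comm], a$months_in_stage[comm],
                               a$age[comm], sex[comm], institutionalization, cl)
          a$residential[comm[u_inst[comm] < p_inst]] <- TRUE
        }
        ## mortality; trailing decline rate is 0 during the first year
        hist <- hist_list[[arm_name]]
        decline <- if (t > decline_window) {
          pmax(0, hist[idx, slot] - a$mmse[idx]) / (decline_window * frac)
        } else rep(0, length(idx))
        hist[idx, slot] <- a$mmse[idx]
        hist_list[[arm_name]] <- hist
        p_mort <- .mortality_prob(a$age[idx], sex[idx], a$mmse[idx], mmse0[idx],
                                  decline, mortality, cl)
        a$alive[idx[u_mort[idx] < p_mort]] <- FALSE
        a$decline_last <- decline  # length(idx); only used by record path

        ## accrual for patients alive at end of cycle
        live <- idx[a$alive[idx]]
        if (length(live)) {
          res <- a$residential[live]
          u_p <- .patient_utility(a$mmse[live], a$npi[live], res,
                                  !res & has_cg[live], utilities)
          a$q_pat[live] <- a$q_pat[live] + u_p * frac * df_t
          a$ly[live] <- a$ly[live] + frac * df_t
          a$occ[cbind(live, a$stage_idx[live])] <-
            a$occ[cbind(live, a$stage_idx[live])] + frac * df_t
          st <- a$stage_idx[live]
          a$c_phc[live] <- a$c_phc[live] + phc_m[st] * cl * df_t
          a$c_pnhc[live] <- a$c_pnhc[live] + pnhc_m[st] * cl * df_t
          a$c_chc[live] <- a$c_chc[live] + ifelse(res, 0, chc_m[st]) * cl * df_t
          a$c_cprod[live] <- a$c_cprod[live] + ifelse(res, 0, cprod_m[st]) * cl * df_t
          if (arm_name == "trt" && drug_m > 0) {
            on <- live[a$on_treatment[live]]
            a$c_drug[on] <- a$c_drug[on] + drug_m * df_t
          }
        }
      }
      ## caregiver accrual runs to the patient's horizon: patient-linked
      ## weight in community, population norm once institutionalized or dead
      cg <- which(has_cg & (t <= horizon))
      if (length(cg)) {
        w <- .caregiver_utility(a$alive[cg], a$residential[cg], a$stage_idx[cg],
                                a$mmse[cg], cg_age0[cg] + t * frac, utilities)
        a$q_cg[cg] <- a$q_cg[cg] + w * frac * df_t
      }
      if (record) {
        rec[[arm_name]][[t]] <- data.frame(
          cycle = t, age = a$age[1], mmse = a$mmse[1], cdrsb = a$cdrsb[1],
          npi = a$npi[1], stage = AD_STAGES[a$stage_idx[1]],
          location = if (a$residential[1]) "residential" else "community",
          alive = a$alive[1], on_treatment = a$on_treatment[1],
          months_in_stage = a$months_in_stage[1])
      }
    }
  }

  trt <- arms$trt; ctl <- arms$ctl
  if (pricing$mode == "one_time") {
    trt$c_drug <- rep(one_time_charge(pricing), n)  # cycle 0, discount 1
    ctl$c_drug <- numeric(n)
  }
  per_patient <- data.frame(
    id = cohort$id,
    qaly_patient_trt = trt$q_pat, qaly_patient_ctl = ctl$q_pat,
    qaly_caregiver_trt = trt$q_cg, qaly_caregiver_ctl = ctl$q_cg,
    ly_trt = trt$ly, ly_ctl = ctl$ly,
    cost_drug_trt = trt$c_drug, cost_drug_ctl = ctl$c_drug,
    cost_patient_healthcare_trt = trt$c_phc, cost_patient_healthcare_ctl = ctl$c_phc,
    cost_patient_nonhealthcare_trt = trt$c_pnhc, cost_patient_nonhealthcare_ctl = ctl$c_pnhc,
    cost_caregiver_healthcare_trt = trt$c_chc, cost_caregiver_healthcare_ctl = ctl$c_chc,
    cost_caregiver_productivity_trt = trt$c_cprod, cost_caregiver_productivity_ctl = ctl$c_cprod)
  occupancy <- rbind(
    data.frame(arm = "trt", stage = AD_STAGES,
               discounted_years = colMeans(trt$occ)),
    data.frame(arm = "ctl", stage = AD_STAGES,
               discounted_years = colMeans(ctl$occ)))
  out <- structure(
    list(per_patient = per_patient, occupancy = occupancy,
         n = n, seed = as.integer(seed), discount_rate = discount_rate,
         cycle_length = cl, max_age = max_age, paired = paired,
         pricing = pricing,
         treatment_effect = prog$treatment_effect),
    class = "ad_pair_set")
  if (record) {
    out$trajectories <- list(
      treated = do.call(rbind, rec$trt),
      untreated = do.call(rbind, rec$ctl))
  }
  out
}

#' @export
print.ad_pair_set <- function(x, ...) {
  cat(sprintf("<paired microsimulation> n = %d patients, seed %d, %s streams\n",
              x$n, x$seed, if (x$paired) "common" else "independent"))
  cat(sprintf("  treatment effect %.3f (CDR-SB slope reduction), pricing: %s\n",
              x$treatment_effect, x$pricing$mode))
  inc_q <- mean(x$per_patient$qaly_patient_trt - x$per_patient$qaly_patient_ctl)
  cat(sprintf("  mean incremental patient QALYs (discounted): %.4f\n", inc_q))
  invisible(x)
}

#' Simulate one patient under treatment and usual care
#'
#' A single-patient wrapper around [simulate_cohort_pairs()] with full
#' per-cycle trajectory recording. Both arms consume identical random draws,
#' so with a null treatment effect the two trajectories are identical
#' cycle-by-cycle.
#'
#' @param baseline a one-row `ad_cohort` data.frame (or a list with the same
#'   fields: `id, age, sex, mmse0, cdrsb0, npi0, has_caregiver,
#'   caregiver_age`).
#' @param ... parameters forwarded to [simulate_cohort_pairs()].
#' @param seed integer seed.
#' @return a list of class `ad_patient_pair` with elements `treated` and
#'   `untreated` (per-cycle data.frames) and `aggregates` (the
#'   `ad_pair_set`).
#' @export
simulate_patient_pair <- function(baseline, ..., seed = 1L) {
  if (!is.data.frame(baseline)) baseline <- as.data.frame(baseline)
  stopifnot(nrow(baseline) == 1L)
  ps <- simulate_cohort_pairs(baseline, ..., seed = seed, record = TRUE)
  structure(list(treated = ps$trajectories$treated,
                 untreated = ps$trajectories$untreated,
                 aggregates = ps),
            class = "ad_patient_pair")
}

#' Re-price stored trajectories as a one-time treatment
#'
#' Drug price does not feed back into disease dynamics, so a one-time pricing
#' scenario reuses the stored trajectory aggregates unchanged and replaces
#' the treatment arm's discounted drug cost with the full price charged at
#' cycle 0 (discount factor exactly 1).
#'
#' @param pairs an `ad_pair_set`.
#' @param price one-time price in $.
#' @return the modified `ad_pair_set`.
#' @export
as_one_time <- function(pairs, price) {
  stopifnot(inherits(pairs, "ad_pair_set"))
  if (price < 0) stop("price must be >= 0", call. = FALSE)
  pairs$per_patient$cost_drug_trt <- rep(price, pairs$n)
  pairs$per_patient$cost_drug_ctl <- rep(0, pairs$n)
  pairs$pricing <- drug_pricing(mode = "one_time", one_time_price = price,
                                effect_scale = pairs$pricing$effect_scale)
  pairs
}
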