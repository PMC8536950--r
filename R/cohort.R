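## Synthetic baseline cohort: an ADNI-like MCI population (MMSE 24-30 at entry
## with a clinician MCI assessment). Distributional defaults are documented
## modelling assumptions, not published values; everything is overridable.

COHORT_COLUMNS <- c("id", "age", "sex", "mmse0", "cdrsb0", "npi0",
                    "has_caregiver", "caregiver_age")

#' Configuration of the synthetic MCI cohort generator
#'
#' Defaults describe a plausible amnestic-MCI trial/registry population:
#' age truncated-normal(73, 7) on \[55, 90\], 45% female, baseline MMSE uniform
#' over 24-30 (the MCI inclusion band), CDR-SB truncated-normal(1.5, 1.0) on
#' \[0.5, 4\], NPI truncated-normal(3, 3) at or above 0, and exactly one informal
#' caregiver per patient, 3 years younger than the patient.
#'
#' @param n cohort size (>= 1).
#' @param seed integer RNG seed; the generated cohort is a deterministic
#'   function of the full config including `seed`.
#' @param age_mean,age_sd,age_bounds age distribution (years), truncated normal.
#' @param prop_female proportion female in \[0, 1\].
#' @param mmse_weights 7 probabilities over MMSE scores 24..30; must sum to 1
#'   (tolerance 1e-9).
#' @param cdrsb_mean,cdrsb_sd,cdrsb_bounds baseline CDR-SB distribution.
#' @param npi_mean,npi_sd,npi_lower baseline NPI distribution (truncated below).
#' @param prop_with_caregiver proportion of patients with a caregiver.
#' @param caregiver_age_offset caregiver age minus patient age (years).
#' @return an object of class `ad_cohort_config`.
#' @export
cohort_config <- function(n = 1000L, seed = 20211022L,
                          age_mean = 73, age_sd = 7, age_bounds = c(55, 90),
                          prop_female = 0.45,
                          mmse_weights = rep(1 / 7, 7),
                          cdrsb_mean = 1.5, cdrsb_sd = 1.0,
                          cdrsb_bounds = c(0.5, 4.0),
                          npi_mean = 3, npi_sd = 3, npi_lower = 0,
                          prop_with_caregiver = 1.0,
                          caregiver_age_offset = -3) {
  bad <- function(field, msg) {
    stop(sprintf("invalid cohort config: field '%s' %s", field, msg), call. = FALSE)
  }
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) bad("n", "must be an integer >= 1")
  if (length(seed) != 1 || is.na(seed)) bad("seed", "must be a single integer")
  if (age_sd < 0) bad("age_sd", "must be >= 0")
  if (length(age_bounds) != 2 || age_bounds[1] > age_bounds[2]) {
    bad("age_bounds", "must be c(lower, upper) with lower <= upper")
  }
  if (prop_female < 0 || prop_female > 1) bad("prop_female", "must be in [0, 1]")
  if (length(mmse_weights) != 7) bad("mmse_weights", "must have 7 entries (scores 24..30)")
  if (any(mmse_weights < 0)) bad("mmse_weights", "must be non-negative")
  if (abs(sum(mmse_weights) - 1) > 1e-9) bad("mmse_weights", "must sum to 1 (tol 1e-9)")
  if (cdrsb_sd < 0) bad("cdrsb_sd", "must be >= 0")
  if (length(cdrsb_bounds) != 2 || cdrsb_bounds[1] > cdrsb_bounds[2] ||
      cdrsb_bounds[1] < 0 || cdrsb_bounds[2] > CDRSB_MAX) {
    bad("cdrsb_bounds", "must lie within [0, 18] with lower <= upper")
  }
  if (npi_sd < 0) bad("npi_sd", "must be >= 0")
  if (npi_lower < 0) bad("npi_lower", "must be >= 0")
  if (prop_with_caregiver < 0 || prop_with_caregiver > 1) {
    bad("prop_with_caregiver", "must be in [0, 1]")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
         prop_female = prop_female, mmse_weights = mmse_weights,
         cdrsb_mean = cdrsb_mean, cdrsb_sd = cdrsb_sd, cdrsb_bounds = cdrsb_bounds,
         npi_mean = npi_mean, npi_sd = npi_sd, npi_lower = npi_lower,
         prop_with_caregiver = prop_with_caregiver,
         caregiver_age_offset = caregiver_age_offset),
    class = "ad_cohort_config")
}

## Inverse-CDF truncated normal draw: deterministic given the RNG stream and
## well-behaved for sd = 0 (returns the clamped mean).
rtruncnorm_icdf <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

#' Generate a synthetic baseline MCI cohort
#'
#' Draws `config$n` baseline patient records. Every generated record satisfies
#' the MCI inclusion rule 24 <= MMSE <= 30; CDR-SB and NPI are truncated at
#' their configured bounds. The result is byte-identical across runs with the
#' same config (including seed).
#'
#' @param config an [cohort_config()] object.
#' @return a `data.frame` of class `ad_cohort` with columns `id`, `age`, `sex`
#'   (factor female/male), `mmse0`, `cdrsb0`, `npi0`, `has_caregiver`,
#'   `caregiver_age`.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 5, seed = 1))
#' range(coh$mmse0)  # within 24..30
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "ad_cohort_config"))
  n <- config$n
  old <- .Random.seed_exists()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  age <- rtruncnorm_icdf(n, config$age_mean, config$age_sd,
                         config$age_bounds[1], config$age_bounds[2])
  sex <- factor(ifelse(stats::runif(n) < config$prop_female, "female", "male"),
                levels = c("female", "male"))
  mmse0 <- sample(24:30, n, replace = TRUE, prob = config$mmse_weights)
  cdrsb0 <- rtruncnorm_icdf(n, config$cdrsb_mean, config$cdrsb_sd,
                            config$cdrsb_bounds[1], config$cdrsb_bounds[2])
  npi0 <- rtruncnorm_icdf(n, config$npi_mean, config$npi_sd, config$npi_lower, Inf)
  has_caregiver <- stats::runif(n) < config$prop_with_caregiver
  caregiver_age <- ifelse(has_caregiver, age + config$caregiver_age_offset, NA_real_)
  out <- data.frame(id = seq_len(n), age = age, sex = sex, mmse0 = mmse0,
                    cdrsb0 = cdrsb0, npi0 = npi0, has_caregiver = has_caregiver,
                    caregiver_age = caregiver_age)
  class(out) <- c("ad_cohort", "data.frame")
  out
}

## Save/restore the global RNG state so generation doesn't perturb the caller.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

validate_cohort_df <- function(df, origin = "cohort") {
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", origin,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop(sprintf("%s: no records", origin), call. = FALSE)
  check <- function(ok, field) {
    bad_rows <- which(!ok)
    if (length(bad_rows)) {
      stop(sprintf("%s: row %d: field '%s' out of range", origin,
                   bad_rows[1], field), call. = FALSE)
    }
  }
  check(!is.na(df$mmse0) & df$mmse0 >= 24 & df$mmse0 <= 30, "mmse0")
  check(!is.na(df$cdrsb0) & df$cdrsb0 >= 0 & df$cdrsb0 <= CDRSB_MAX, "cdrsb0")
  check(!is.na(df$npi0) & df$npi0 >= 0, "npi0")
  check(df$sex %in% c("female", "male"), "sex")
  check(!is.na(df$age) & df$age > 0, "age")
  check(!is.na(df$has_caregiver), "has_caregiver")
  invisible(df)
}

#' Read / write a baseline cohort as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with a header naming every baseline
#' field (`id, age, sex, mmse0, cdrsb0, npi0, has_caregiver, caregiver_age`),
#' "." as decimal separator. `read_cohort(write_cohort(x, p))` is the identity
#' on valid cohorts; malformed rows are rejected with their row number.
#'
#' @param path file path.
#' @param cohort an `ad_cohort` data.frame (as from [generate_cohort()]).
#' @return `read_cohort` returns an `ad_cohort` data.frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop(sprintf("%s: no records", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(sprintf("%s: no records", path), call. = FALSE)
  df <- validate_cohort_df(df, origin = path)
  df <- df[COHORT_COLUMNS]
  df$sex <- factor(df$sex, levels = c("female", "male"))
  df$has_caregiver <- as.logical(df$has_caregiver)
  class(df) <- c("ad_cohort", "data.frame")
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort_df(cohort)
  utils::write.csv(as.data.frame(cohort)[COHORT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
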