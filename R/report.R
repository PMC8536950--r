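## Human-readable report tables mirroring the perspective table (ICERs by
## scenario A-F) and the administration/price table, plus CSV export.
## Text reports group thousands with a thin space ("183 000"); CSVs carry
## plain numbers.

#' Format a dollar amount with thin-space thousands grouping
#'
#' @param x numeric.
#' @param round_to round to this unit first (e.g. 1000 for ICER tables);
#'   default 1 (cents dropped).
#' @return character.
#' @export
format_dollars <- function(x, round_to = 1) {
  fmt1 <- function(v) {
    if (is.na(v)) return(NA_character_)
    v <- round(v / round_to) * round_to
    s <- format(abs(round(v)), big.mark = "\u2009", scientific = FALSE, trim = TRUE)
    paste0(if (v < 0) "-$" else "$", s)
  }
  vapply(x, fmt1, character(1))
}

icer_cell <- function(icer, label) {
  ifelse(label == "icer", format_dollars(icer, round_to = 1000),
         ifelse(label == "dominant", "dominant",
                ifelse(label == "dominated", "dominated", label)))
}

#' Render the scenario-suite report
#'
#' Produces the perspective table (one ICER row, scenario columns A-F,
#' rounded to the nearest $1,000), the one-time/repeated pricing table, and a
#' component breakdown appendix. The same values are available as plain
#' data.frames via [report_tables()].
#'
#' @param suite an `ad_cea_suite` from [run_scenario_suite()].
#' @return a character vector of report lines.
#' @export
render_report <- function(suite) {
  stopifnot(inherits(suite, "ad_cea_suite"))
  st <- suite$scenario_table
  lines <- c(
    sprintf("ICER by analytic perspective ($/QALY, nearest $1,000; n = %d, seed %d)",
            suite$n, suite$seed),
    paste(formatC(st$scenario, width = 12), collapse = ""),
    paste(formatC(icer_cell(st$icer, st$icer_label), width = 12), collapse = ""),
    "",
    "ICER by drug administration and price ($/QALY, nearest $1,000)")
  ot <- suite$onetime
  for (i in seq_len(nrow(ot))) {
    lines <- c(lines, sprintf("  %-38s %s", ot$label[i],
                              icer_cell(ot$icer[i], ot$icer_label[i])))
  }
  lines <- c(lines, "", "Incremental component breakdown (scenario F, $):")
  f <- suite$scenarios[["F"]]
  if (!is.null(f)) {
    for (nm in names(f$incremental_cost_components)) {
      lines <- c(lines, sprintf("  %-26s %12s", nm,
                                format_dollars(f$incremental_cost_components[[nm]])))
    }
    lines <- c(lines, sprintf("  %-26s %12s", "total",
                              format_dollars(f$incremental_cost)))
  }
  c(lines, "", sprintf("config hash %s", suite$config_hash))
}

#' Machine-readable report tables
#'
#' @param suite an `ad_cea_suite`.
#' @return a list of data.frames: `scenarios` (one row per perspective with
#'   incremental values and raw ICERs) and `onetime` (the pricing sweep).
#'   ICERs here are unrounded; rounding to the nearest $1,000 is a
#'   presentation choice of [render_report()].
#' @export
report_tables <- function(suite) {
  stopifnot(inherits(suite, "ad_cea_suite"))
  list(scenarios = suite$scenario_table, onetime = suite$onetime)
}

#' Write the report tables as CSV (plus a JSON metadata sidecar)
#'
#' @param suite an `ad_cea_suite`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_report_csv <- function(suite, dir) {
  stopifnot(inherits(suite, "ad_cea_suite"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- report_tables(suite)
  utils::write.csv(tabs$scenarios, file.path(dir, "scenarios.csv"), row.names = FALSE)
  utils::write.csv(tabs$onetime, file.path(dir, "onetime.csv"), row.names = FALSE)
  meta <- list(seed = suite$seed, n = suite$n, config_hash = suite$config_hash)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}
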