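#' Round half away from zero
#'
#' Published tables round 0.5 up (so 2.25% at one decimal prints 2.3%),
#' unlike base R's round-half-to-even. A tiny relative nudge guards against
#' binary representation of values sitting exactly on a half.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a proportion as a printed percentage
#' @param p Proportion in `[0, 1]` (or `NA`).
#' @param digits Decimal places of the percentage.
#' @return Character vector like `"5.7%"`; `""` for `NA`.
#' @export
format_pct <- function(p, digits = 1) {
  ifelse(is.na(p), "",
         sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * p, digits)))
}

#' Mask small cells for disclosure control
#'
#' Cells whose case count is positive but below the threshold (default 10)
#' have both the displayed count and the displayed proportion replaced by a
#' mask marker, to prevent re-identification of small groups. Zero counts and
#' counts at or above the threshold display normally. Masking is a display
#' operation only: the raw `cases`/`proportion` columns are retained and all
#' estimation upstream uses raw counts.
#'
#' @param tbl Tibble with `cases` (integer) and `proportion` columns, e.g.
#'   from [annual_prevalence_table()].
#' @param threshold Counts strictly below this (and above 0) are masked.
#' @param marker Mask marker string.
#' @param digits Decimal places for displayed percentages.
#' @return `tbl` with added `cases_display` and `proportion_display`
#'   character columns.
#' @export
#' @examples
#' mask_small_cells(tibble::tibble(cases = c(0L, 9L, 10L),
#'                                 proportion = c(0, .09, .1)))
mask_small_cells <- function(tbl, threshold = 10L, marker = "―",
                             digits = 1) {
  if (!all(c("cases", "proportion") %in% names(tbl))) {
    stop("`tbl` must have `cases` and `proportion` columns")
  }
  if (threshold < 1L) stop("`threshold` must be >= 1")
  masked <- tbl$cases > 0L & tbl$cases < threshold
  tbl$cases_display <- ifelse(masked, marker, sprintf("(%d)", tbl$cases))
  tbl$proportion_display <- ifelse(masked, marker,
                                   format_pct(tbl$proportion, digits))
  tbl
}

#' Write the report file set for one pipeline run
#'
#' Writes publication-shaped outputs to `outdir`:
#' `table1.csv` (per-FY open-population prevalence/utilization, masked),
#' `table2.csv` (fixed-denominator cumulative prevalence series),
#' `table3.csv` (per-stratum annual incidence slopes, as percentages),
#' `estimates.json` (pooled and model estimates with CI), and
#' `run_log.txt` (continuity/exclusion counts, ignored claims, masked cells).
#'
#' @param estimates Tibble of incidence estimates (rows from
#'   [pooled_slope()] / [fit_weighted_model()] / [incidence_slope()]).
#' @param tables Named list with any of `table1` (from
#'   [annual_prevalence_table()]), `table2` (series tibble), `table3` (from
#'   [incidence_table()]).
#' @param outdir Output directory (created if missing).
#' @param log_lines Extra character lines for the run log (e.g. continuity
#'   counts).
#' @param threshold,marker Masking parameters, see [mask_small_cells()].
#' @return Invisibly, a tibble manifest (`file`, `description`).
#' @export
render_reports <- function(estimates, tables, outdir, log_lines = character(),
                           threshold = 10L, marker = "―") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  add <- function(file, desc) {
    manifest <<- dplyr::bind_rows(manifest,
                                  tibble::tibble(file = file, description = desc))
  }
  n_masked <- 0L

  if (!is.null(tables$table1)) {
    t1 <- mask_small_cells(tables$table1, threshold = threshold,
                           marker = marker)
    n_masked <- n_masked + sum(t1$cases_display == marker)
    readr::write_csv(t1, file.path(outdir, "table1.csv"))
    add("table1.csv", "per-FY prevalence/utilization, open population, masked")
  }
  if (!is.null(tables$table2)) {
    t2 <- tables$table2
    t2$proportion_display <- format_pct(t2$proportion, 1)
    readr::write_csv(t2, file.path(outdir, "table2.csv"))
    add("table2.csv", "fixed-denominator cumulative prevalence series")
  }
  if (!is.null(tables$table3)) {
    t3 <- tables$table3
    t3$incidence_pct <- round_half_up(100 * t3$slope, 2)
    readr::write_csv(t3, file.path(outdir, "table3.csv"))
    add("table3.csv", "annual incidence slopes by stratum (% per year)")
  }

  est <- as.list(estimates)
  jsonlite::write_json(
    lapply(seq_len(nrow(estimates)), function(i) as.list(estimates[i, ])),
    file.path(outdir, "estimates.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  add("estimates.json", "incidence estimates with standard errors and CIs")

  log <- c(sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           log_lines,
           sprintf("masked cells in table1: %d", n_masked))
  writeLines(log, file.path(outdir, "run_log.txt"))
  add("run_log.txt", "inclusion/exclusion and masking log")

  invisible(manifest)
}

#' Format continuity counts for the run log
#' @param counts Named integer vector, the `"continuity_counts"` attribute of
#'   [build_cohort()] output.
#' @return Character vector of log lines.
#' @export
continuity_log_lines <- function(counts) {
  c("ledger persons by continuity status:",
    sprintf("  %-12s %d", names(counts), counts))
}
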