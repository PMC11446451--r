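#' Run the full person-level pipeline
#'
#' Ledger + claims in, estimates out: builds the fixed cohort (continuity
#' filter), ascertains carried-forward disease status and yearly utilization,
#' computes the per-FY open-population table, the fixed-denominator
#' cumulative prevalence series, per-stratum incidence slopes, the pooled
#' slope and the denominator-weighted model estimate.
#'
#' @param ledger Ledger tibble (see [build_cohort()]).
#' @param claims Claims tibble (see [yearly_diagnosis_flags()]).
#' @param window A [study_window()].
#' @param codes A [code_set()].
#' @return List: `cohort`, `status` (carried-forward matrix), `table1`
#'   (per-FY open-population measures), `series` (cumulative prevalence),
#'   `table3` (per-stratum slopes), `estimates` (pooled + model rows),
#'   `log_lines` (continuity and ignored-claim counts).
#' @export
run_pipeline <- function(ledger, claims, window = study_window(),
                         codes = code_set()) {
  cohort <- build_cohort(ledger, window)
  persons <- cohort$person_id

  raw <- yearly_diagnosis_flags(claims, codes, window, persons)
  status <- carry_forward(raw)
  med <- utilization_flags(claims, codes, window, "medication", persons)
  ins <- utilization_flags(claims, codes, window, "insulin", persons)

  population <- open_population(ledger, window)
  pop_ids <- sort(unique(population$person_id))
  table1 <- annual_prevalence_table(
    population,
    list(PR = yearly_diagnosis_flags(claims, codes, window, pop_ids),
         MU = utilization_flags(claims, codes, window, "medication", pop_ids),
         IU = utilization_flags(claims, codes, window, "insulin", pop_ids))
  )

  series <- cumulative_prevalence_series(status, cohort)
  table3 <- incidence_table(series)
  estimates <- dplyr::bind_rows(pooled_slope(series),
                                fit_weighted_model(series))

  list(
    cohort = cohort, status = status, table1 = table1, series = series,
    table3 = table3, estimates = estimates,
    log_lines = c(
      continuity_log_lines(attr(cohort, "continuity_counts")),
      sprintf("cohort size (fixed denominator): %d", nrow(cohort)),
      sprintf("claims ignored (outside window/cohort): %d",
              attr(raw, "n_ignored"))
    )
  )
}

#' Estimate incidence from pre-aggregated stratum counts
#'
#' The aggregate-ingest path: takes a wide stratum-count table (fixed
#' denominators plus cumulative case counts per fiscal year, e.g. a
#' published table or [table2_replica()]) and returns the per-stratum
#' slopes, the pooled slope and the weighted-model estimate without touching
#' person-level data.
#'
#' @param counts Wide counts tibble for [series_from_counts()].
#' @return List: `series`, `table3`, `estimates`.
#' @export
estimate_from_aggregates <- function(counts) {
  series <- series_from_counts(counts)
  list(series = series,
       table3 = incidence_table(series),
       estimates = dplyr::bind_rows(pooled_slope(series),
                                    fit_weighted_model(series)))
}
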