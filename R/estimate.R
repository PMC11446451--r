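#' Ordinary least-squares slope of cumulative prevalence
#'
#' Annual incidence is estimated as the slope of cumulative ("up to")
#' prevalence against fiscal-year index, by ordinary least squares:
#' `sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)`, the same
#' quantity a spreadsheet SLOPE function returns. The slope is invariant to
#' affine recodings of the year index, so 0..4 vs 2015..2019 makes no
#' difference.
#'
#' @param proportions Numeric vector of cumulative prevalence proportions,
#'   one per fiscal year in order (length >= 2).
#' @param label Label carried into the result (stratum name, "overall", ...).
#' @return One-row tibble: `label`, `slope` (proportion per year), `se`
#'   (OLS standard error of the slope), `ci_low`, `ci_high` (`NA`: no
#'   interval is attached to single-series slopes; see
#'   [fit_weighted_model()] for the pooled interval).
#' @export
#' @examples
#' incidence_slope(c(67, 86, 108, 129, 149) / 1148) # 0.0180...
incidence_slope <- function(proportions, label = "series") {
  y <- as.numeric(proportions)
  if (length(y) < 2L) stop("need at least 2 yearly proportions to fit a slope")
  if (any(!is.finite(y))) stop("`proportions` must be finite")
  x <- seq_along(y) - 1
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  res <- y - mean(y) - slope * xc
  se <- if (length(y) > 2L) sqrt(sum(res^2) / (length(y) - 2L) / sxx) else NA_real_
  tibble::tibble(label = label, slope = slope, se = se,
                 ci_low = NA_real_, ci_high = NA_real_)
}

#' Fixed-denominator cumulative prevalence series by stratum
#'
#' For each sex x age-band stratum of the fixed cohort, counts the members
#' ever diagnosed by each fiscal year. The denominator is the stratum's
#' baseline (first-FY) cohort size in every year — members who died keep
#' their last disease status and stay in the denominator — so the series is
#' non-decreasing by construction. An `"All"/"All"` aggregate row set (summed
#' counts over summed denominators) is appended.
#'
#' @param status Logical matrix of carried-forward ever-diagnosed status
#'   (persons x fiscal years), as from [carry_forward()]. Row names must be
#'   exactly the cohort's person ids.
#' @param cohort Tibble from [build_cohort()].
#' @param include_overall Append the all-strata aggregate rows?
#' @return Tibble with one row per stratum x fiscal year: `sex`, `age_band`,
#'   `fiscal_year`, `n` (fixed denominator), `count`, `proportion`.
#' @export
cumulative_prevalence_series <- function(status, cohort,
                                         include_overall = TRUE) {
  if (is.null(rownames(status)) ||
      !setequal(rownames(status), cohort$person_id) ||
      nrow(status) != nrow(cohort)) {
    stop("status matrix rows must match the cohort person ids exactly")
  }
  fys <- as.integer(colnames(status))
  status <- status[match(cohort$person_id, rownames(status)), , drop = FALSE]

  key <- paste(cohort$sex, cohort$age_band, sep = "\r")
  counts <- rowsum(status + 0L, key)
  n_strat <- as.vector(table(key)[rownames(counts)])
  parts <- do.call(rbind, strsplit(rownames(counts), "\r", fixed = TRUE))

  out <- tibble::tibble(
    sex = rep(parts[, 1L], each = length(fys)),
    age_band = rep(parts[, 2L], each = length(fys)),
    fiscal_year = rep(fys, times = nrow(counts)),
    n = rep(n_strat, each = length(fys)),
    count = as.integer(t(counts))
  )
  if (include_overall) {
    overall <- tibble::tibble(
      sex = "All", age_band = "All", fiscal_year = fys,
      n = nrow(cohort), count = as.integer(colSums(status))
    )
    out <- dplyr::bind_rows(out, overall)
  }
  out$proportion <- ifelse(out$n > 0, out$count / out$n, NA_real_)
  dplyr::arrange(out, .data$sex != "All",
                 factor(.data$sex, levels = c("M", "F", "All")),
                 factor(.data$age_band, levels = c(age_band_levels(), "All")),
                 .data$fiscal_year)
}

strata_only <- function(series) {
  dplyr::filter(series, .data$sex != "All" | .data$age_band != "All")
}

#' Per-stratum annual incidence slopes
#'
#' Fits [incidence_slope()] within each sex x age-band stratum of a
#' cumulative prevalence series (aggregate `"All"` rows are ignored).
#'
#' @param series Tibble from [cumulative_prevalence_series()] or
#'   [series_from_counts()].
#' @return Tibble: `sex`, `age_band`, `n`, `slope` (proportion per year).
#' @export
incidence_table <- function(series) {
  ser <- dplyr::arrange(strata_only(series), .data$fiscal_year)
  dplyr::summarise(
    dplyr::group_by(ser, .data$sex, .data$age_band),
    n = .data$n[1L],
    slope = incidence_slope(.data$proportion)$slope,
    .groups = "drop"
  )
}

#' Pooled annual incidence from the aggregated series
#'
#' The overall annual incidence without stratification: stratum counts and
#' fixed denominators are summed per fiscal year and the OLS slope of the
#' resulting overall cumulative prevalence is taken. Under fixed
#' denominators this equals the denominator-weighted mean of the per-stratum
#' slopes exactly.
#'
#' @inheritParams incidence_table
#' @return One-row tibble as from [incidence_slope()], labelled `"overall"`.
#' @export
pooled_slope <- function(series) {
  ser <- strata_only(series)
  if (!nrow(ser)) stop("empty series")
  agg <- dplyr::summarise(
    dplyr::group_by(ser, .data$fiscal_year),
    count = sum(.data$count), n = sum(.data$n), .groups = "drop"
  )
  agg <- dplyr::arrange(agg, .data$fiscal_year)
  incidence_slope(agg$count / agg$n, label = "overall")
}

#' Denominator-weighted linear model for the pooled annual increase
#'
#' Fits a Gaussian identity-link linear model to the stratum-year cumulative
#' prevalence proportions: `proportion ~ year_index + age_band * sex`,
#' weighted by the stratum's fixed denominator. Age band, sex and their
#' interaction absorb the stratum baseline levels; the single `year_index`
#' coefficient is the pooled annual increase in prevalence, i.e. the pooled
#' annual incidence. A Wald 95% interval (`coefficient +/- 1.96 * SE`) is
#' attached. Because weights are constant within stratum and the year design
#' is balanced, the year coefficient equals the denominator-weighted mean of
#' the per-stratum OLS slopes.
#'
#' Factors with fewer than two observed levels (e.g. a single-sex input) are
#' dropped from the formula; with a single stratum the model reduces to that
#' stratum's OLS fit.
#'
#' @inheritParams incidence_table
#' @return One-row tibble: `label = "model"`, `slope`, `se`, `ci_low`,
#'   `ci_high` (proportions per year).
#' @export
fit_weighted_model <- function(series) {
  ser <- strata_only(series)
  if (!nrow(ser)) stop("empty series")
  ser <- dplyr::arrange(ser, .data$sex, .data$age_band, .data$fiscal_year)
  dat <- data.frame(
    proportion = ser$proportion,
    year_index = ser$fiscal_year - min(ser$fiscal_year),
    age_band = factor(ser$age_band),
    sex = factor(ser$sex),
    n = ser$n
  )
  terms <- "year_index"
  if (nlevels(dat$age_band) > 1L) terms <- c(terms, "age_band")
  if (nlevels(dat$sex) > 1L) terms <- c(terms, "sex")
  if (nlevels(dat$age_band) > 1L && nlevels(dat$sex) > 1L) {
    terms <- c(terms, "age_band:sex")
  }
  fml <- stats::reformulate(terms, response = "proportion")
  fit <- stats::lm(fml, data = dat, weights = n)
  est <- stats::coef(fit)[["year_index"]]
  se <- sqrt(stats::vcov(fit)["year_index", "year_index"])
  tibble::tibble(label = "model", slope = est, se = se,
                 ci_low = est - 1.96 * se, ci_high = est + 1.96 * se)
}

#' Per-fiscal-year prevalence and utilization over the open population
#'
#' Descriptive per-FY measures over each year's enrolled persons (the open
#' population, not the fixed cohort): the share with a raw (non-carried-
#' forward) diagnosis flag, a medication flag, or an insulin flag in that
#' year, by sex and frozen baseline age band.
#'
#' @param population Tibble from [open_population()]: one row per person x
#'   enrolled fiscal year with `sex` and `age_band`.
#' @param flags Named list of logical flag matrices (persons x fiscal years),
#'   e.g. `list(PR = raw_diagnosis, MU = medication, IU = insulin)`. Persons
#'   absent from a matrix count as unflagged.
#' @return Tibble: `sex`, `age_band`, `fiscal_year`, `measure`, `n`,
#'   `cases`, `proportion` (`NA` where `n = 0`).
#' @export
annual_prevalence_table <- function(population, flags) {
  stopifnot(is.list(flags), !is.null(names(flags)))
  long <- NULL
  for (measure in names(flags)) {
    m <- flags[[measure]]
    i <- match(population$person_id, rownames(m))
    j <- match(as.character(population$fiscal_year), colnames(m))
    val <- ifelse(is.na(i) | is.na(j), FALSE, m[cbind(i, j)])
    long <- dplyr::bind_rows(long, dplyr::mutate(
      population, measure = measure, flagged = val
    ))
  }
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$sex, .data$age_band, .data$fiscal_year,
                    .data$measure),
    n = dplyr::n(), cases = sum(.data$flagged), .groups = "drop"
  )
  out$proportion <- ifelse(out$n > 0, out$cases / out$n, NA_real_)
  dplyr::arrange(out, factor(.data$sex, levels = c("M", "F")),
                 factor(.data$age_band, levels = age_band_levels(TRUE)),
                 .data$fiscal_year, .data$measure)
}

#' Build a cumulative prevalence series from pre-aggregated stratum counts
#'
#' Ingests a wide table of published or pre-aggregated cumulative case
#' counts — one row per sex x age-band stratum with its fixed denominator
#' `n` and one count column per fiscal year (`fy2015`, `fy2016`, ...) — and
#' returns the long series format used by [incidence_table()],
#' [pooled_slope()] and [fit_weighted_model()]. This bypasses the
#' person-level pipeline stages.
#'
#' @param counts Tibble with columns `sex`, `age_band`, `n` and `fy<YYYY>`
#'   count columns.
#' @return Long series tibble: `sex`, `age_band`, `fiscal_year`, `n`,
#'   `count`, `proportion`.
#' @export
series_from_counts <- function(counts) {
  fy_cols <- grep("^fy\\d{4}$", names(counts), value = TRUE)
  if (length(fy_cols) < 2L) stop("need at least two fy<YYYY> count columns")
  long <- tidyr::pivot_longer(counts, dplyr::all_of(fy_cols),
                              names_to = "fiscal_year", values_to = "count")
  long$fiscal_year <- as.integer(sub("^fy", "", long$fiscal_year))
  long$proportion <- long$count / long$n
  bad <- long$count > long$n
  if (any(bad)) stop("count exceeds denominator for stratum ",
                     paste(unique(long$sex[bad]), unique(long$age_band[bad])))
  dplyr::select(long, "sex", "age_band", "fiscal_year", "n", "count",
                "proportion")
}

#' Published stratum-count replica table
#'
#' The 24 sex x age-band strata of the reference analysis (a five-year
#' municipal insurance cohort, FY2015-FY2019): fixed FY2015 denominators and
#' cumulative ever-diagnosed counts per fiscal year, as shipped in
#' `inst/extdata/table2_replica.csv`.
#'
#' @return Wide counts tibble suitable for [series_from_counts()].
#' @export
table2_replica <- function() {
  path <- system.file("extdata", "table2_replica.csv",
                      package = "claimscohort", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sex = readr::col_character(),
                    age_band = readr::col_character(),
                    .default = readr::col_integer()
                  ))
}
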