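#' Assign 5-year baseline age bands
#'
#' Ages are banded as at the baseline fiscal year and the band is frozen for
#' the whole window: a person aged 63 at baseline belongs to "60-64" in every
#' study year. Bands run 40-44, 45-49, ..., 90-94, with an open-ended "95-"
#' top band. Ages below 40 map to the sentinel band "under-40", which
#' [build_cohort()] excludes.
#'
#' @param age_at_baseline Integer vector of ages (years) at the baseline FY.
#' @return Character vector of band labels.
#' @export
#' @examples
#' assign_age_band(c(63, 40, 44, 45, 97, 39))
assign_age_band <- function(age_at_baseline) {
  age <- as.integer(age_at_baseline)
  if (any(is.na(age))) stop("`age_at_baseline` contains non-integer values")
  if (any(age < 0L)) stop("`age_at_baseline` must be non-negative")
  lo <- pmin((age %/% 5L) * 5L, 95L)
  band <- ifelse(lo >= 95L, "95-", sprintf("%d-%d", lo, lo + 4L))
  ifelse(age < 40L, "under-40", band)
}

#' Ordered factor levels for age bands
#' @param include_under40 Keep the sentinel "under-40" level?
#' @return Character vector of band labels in ascending age order.
#' @export
age_band_levels <- function(include_under40 = FALSE) {
  bands <- c(sprintf("%d-%d", seq(40L, 90L, 5L), seq(44L, 94L, 5L)), "95-")
  if (include_under40) c("under-40", bands) else bands
}

# months covered by one person's spells, as a sorted integer index vector;
# errors on overlap because overlapping spells make continuity ill-defined
covered_months <- function(start_idx, end_idx, person_id) {
  if (any(end_idx < start_idx)) {
    stop("spell_end precedes spell_start for person ", person_id)
  }
  o <- order(start_idx)
  start_idx <- start_idx[o]; end_idx <- end_idx[o]
  if (length(start_idx) > 1L &&
      any(start_idx[-1L] <= end_idx[-length(end_idx)])) {
    stop("overlapping ledger spells for person ", person_id)
  }
  unlist(lapply(seq_along(start_idx), function(i) start_idx[i]:end_idx[i]),
         use.names = FALSE)
}

#' Classify one person's enrollment continuity over the study window
#'
#' The analysis cohort keeps only persons observable for the full window:
#' continuously covered from the first month of the window either to its last
#' month (`continuous`) or to an in-window death (`died_during`). Everyone
#' else is excluded: `late_entry` (first coverage after the window opens),
#' `gap` (a hole in coverage with coverage on both sides), or `left`
#' (coverage stops before the window closes for any reason other than death,
#' e.g. disenrollment on moving away).
#'
#' @param spells Data frame of one person's ledger spells with columns
#'   `spell_start`, `spell_end` ("YYYY-MM") and `end_reason`
#'   (`death`, `disenrollment` or `study_end`).
#' @param window A [study_window()].
#' @return Character scalar: one of `"continuous"`, `"died_during"`,
#'   `"left"`, `"gap"`, `"late_entry"`.
#' @export
#' @examples
#' w <- study_window(2015, 5)
#' full <- data.frame(spell_start = "2015-04", spell_end = "2020-03",
#'                    end_reason = "study_end")
#' assess_continuity(full, w) # "continuous"
assess_continuity <- function(spells, window) {
  stopifnot(inherits(window, "study_window"))
  pid <- if ("person_id" %in% names(spells)) spells$person_id[1] else "<unknown>"
  s <- ym_index(spells$spell_start)
  e <- ym_index(spells$spell_end)
  classify_continuity(s, e, spells$end_reason, pid, window)
}

# core classifier shared by assess_continuity() and build_cohort()
classify_continuity <- function(start_idx, end_idx, end_reason, person_id,
                                window) {
  cov <- covered_months(start_idx, end_idx, person_id)
  cov <- sort(cov[cov >= window$start_month & cov <= window$end_month])
  if (length(cov) == 0L || cov[1L] > window$start_month) {
    return("late_entry")
  }
  # longest contiguous run starting at the window's first month
  breaks <- which(diff(cov) > 1L)
  reach <- if (length(breaks)) cov[breaks[1L]] else cov[length(cov)]
  if (length(breaks)) {
    return("gap")
  }
  # contiguous coverage from window start to `reach`
  last_reason <- end_reason[which.max(end_idx)]
  if (identical(last_reason, "death") && max(end_idx) <= window$end_month) {
    return("died_during")
  }
  if (reach >= window$end_month) "continuous" else "left"
}

validate_ledger <- function(ledger) {
  req <- c("person_id", "sex", "age_at_baseline", "spell_start", "spell_end",
           "end_reason")
  miss <- setdiff(req, names(ledger))
  if (length(miss)) stop("ledger is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(ledger$end_reason),
                 c("death", "disenrollment", "study_end"))
  if (length(bad)) stop("unknown end_reason value(s): ", paste(bad, collapse = ", "))
  bad_sex <- setdiff(unique(ledger$sex), c("M", "F"))
  if (length(bad_sex)) stop("sex must be 'M' or 'F'; found: ", paste(bad_sex, collapse = ", "))
  invisible(ledger)
}

#' Build the fixed analysis cohort from an enrollment ledger
#'
#' Applies the continuity rule over the study window and the baseline age
#' filter (age >= 40 at the first fiscal year). Persons who died during the
#' window are retained (with `death_fy` recorded) so that the cohort
#' denominator stays constant across all study years; movers, gap persons and
#' late entrants are excluded.
#'
#' @param ledger Tibble of enrollment spells, one row per spell, with columns
#'   `person_id`, `sex` (`M`/`F`), `age_at_baseline`, `spell_start`,
#'   `spell_end` ("YYYY-MM") and `end_reason`.
#' @param window A [study_window()].
#' @return Tibble with one row per retained person: `person_id`, `sex`,
#'   `age_band`, `death_fy` (integer or `NA`), `tracked` (always `TRUE`).
#'   The attribute `"continuity_counts"` carries the number of ledger persons
#'   in each continuity status plus `"under_40"` exclusions, for run logs.
#' @export
build_cohort <- function(ledger, window) {
  stopifnot(inherits(window, "study_window"))
  validate_ledger(ledger)

  persons <- dplyr::distinct(ledger, .data$person_id, .data$sex,
                             .data$age_at_baseline)
  dup <- persons$person_id[duplicated(persons$person_id)]
  if (length(dup)) {
    stop("conflicting sex/age for person(s): ",
         paste(unique(dup), collapse = ", "))
  }

  led <- dplyr::mutate(ledger,
                       .start = ym_index(.data$spell_start),
                       .end = ym_index(.data$spell_end))
  by_person <- dplyr::group_by(led, .data$person_id)
  status_tbl <- dplyr::summarise(
    by_person,
    status = classify_continuity(.data$.start, .data$.end, .data$end_reason,
                                 .data$person_id[1L], window),
    death_fy = if (any(.data$end_reason == "death"))
      fy_of_month(max(.data$.end[.data$end_reason == "death"])) else NA_integer_,
    .groups = "drop"
  )

  tab <- dplyr::left_join(persons, status_tbl, by = "person_id")
  keep <- tab$status %in% c("continuous", "died_during")
  under40 <- tab$age_at_baseline < 40L

  counts <- table(factor(tab$status, levels = c("continuous", "died_during",
                                                "left", "gap", "late_entry")))
  counts <- c(as.integer(counts), sum(keep & under40))
  names(counts) <- c("continuous", "died_during", "left", "gap", "late_entry",
                     "under_40")

  cohort <- tab[keep & !under40, , drop = FALSE]
  out <- tibble::tibble(
    person_id = cohort$person_id,
    sex = cohort$sex,
    age_band = assign_age_band(cohort$age_at_baseline),
    death_fy = ifelse(cohort$status == "died_during", cohort$death_fy,
                      NA_integer_),
    tracked = TRUE
  )
  attr(out, "continuity_counts") <- counts
  out
}

#' Per-fiscal-year open population from the ledger
#'
#' The open population behind the per-FY descriptive tables: a person counts
#' as enrolled in a fiscal year if any of their covered months falls in it.
#' No continuity filter is applied; the baseline age filter (>= 40) and the
#' frozen baseline age band are.
#'
#' @inheritParams build_cohort
#' @return Tibble with one row per person x enrolled fiscal year:
#'   `person_id`, `sex`, `age_band`, `fiscal_year`.
#' @export
open_population <- function(ledger, window) {
  stopifnot(inherits(window, "study_window"))
  validate_ledger(ledger)
  led <- ledger[ledger$age_at_baseline >= 40L, , drop = FALSE]
  s <- pmax(ym_index(led$spell_start), window$start_month)
  e <- pmin(ym_index(led$spell_end), window$end_month)
  ok <- s <= e
  led <- led[ok, , drop = FALSE]
  fy_s <- fy_of_month(s[ok]); fy_e <- fy_of_month(e[ok])
  reps <- fy_e - fy_s + 1L
  out <- tibble::tibble(
    person_id = rep(led$person_id, reps),
    sex = rep(led$sex, reps),
    age_band = rep(assign_age_band(led$age_at_baseline), reps),
    fiscal_year = unlist(Map(seq, fy_s, fy_e), use.names = FALSE)
  )
  dplyr::distinct(out)
}
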