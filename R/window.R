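#' Define a fiscal-year study window
#'
#' The study window is a run of consecutive Japanese fiscal years (April
#' through March). The default reproduces a five-year window starting FY2015,
#' i.e. April 2015 through March 2020.
#'
#' @param first_fy Integer label of the first fiscal year (e.g. `2015`).
#' @param n_years Number of fiscal years covered (must be >= 2).
#'
#' @return An object of class `study_window`: a list with `first_fy`,
#'   `n_years`, the vector of fiscal-year labels `fys`, and the month indices
#'   `start_month`/`end_month` delimiting the window (see [ym_index()]).
#' @export
#' @examples
#' study_window(2015, 5)
study_window <- function(first_fy = 2015L, n_years = 5L) {
  first_fy <- as.integer(first_fy)
  n_years <- as.integer(n_years)
  if (is.na(first_fy)) stop("`first_fy` must be an integer fiscal-year label")
  if (is.na(n_years) || n_years < 2L) stop("`n_years` must be an integer >= 2")
  structure(
    list(
      first_fy = first_fy,
      n_years = n_years,
      fys = first_fy + 0:(n_years - 1L),
      start_month = ym_index(sprintf("%d-04", first_fy)),
      end_month = ym_index(sprintf("%d-03", first_fy + n_years))
    ),
    class = "study_window"
  )
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf(
    "<study_window> FY%d-FY%d (%d fiscal years, Apr %d - Mar %d)\n",
    x$first_fy, x$first_fy + x$n_years - 1L, x$n_years,
    x$first_fy, x$first_fy + x$n_years
  ))
  invisible(x)
}

#' Convert "YYYY-MM" month labels to a linear month index
#'
#' @param ym Character vector of months in `"YYYY-MM"` format.
#' @return Integer vector, months since year 0 (`year * 12 + month - 1`).
#' @export
ym_index <- function(ym) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", ym)
  if (any(!ok)) {
    stop("malformed month label(s): ", paste(utils::head(ym[!ok], 3), collapse = ", "),
         " (expected \"YYYY-MM\")")
  }
  y <- as.integer(substr(ym, 1, 4))
  m <- as.integer(substr(ym, 6, 7))
  y * 12L + m - 1L
}

#' Convert a linear month index back to a "YYYY-MM" label
#' @param idx Integer month index as produced by [ym_index()].
#' @return Character vector of `"YYYY-MM"` labels.
#' @export
ym_label <- function(idx) {
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

#' Fiscal year of a calendar month
#'
#' Japanese fiscal years run April through March: 2016-03 belongs to FY2015.
#'
#' @param ym Character vector of `"YYYY-MM"` months, or an integer month index.
#' @return Integer fiscal-year labels.
#' @export
#' @examples
#' fy_of_month(c("2015-04", "2016-03", "2016-04")) # 2015 2015 2016
fy_of_month <- function(ym) {
  idx <- if (is.character(ym)) ym_index(ym) else as.integer(ym)
  (idx - 3L) %/% 12L
}
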