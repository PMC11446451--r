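#' Claim code definitions for case ascertainment
#'
#' Diagnosis codes are matched by ICD-10 prefix: the defaults E11-E14 cover
#' the type II / other / malnutrition-related / unspecified diabetes mellitus
#' categories, so "E11.9" matches prefix "E11". Diabetes medication is
#' identified by the first three digits of the Japanese drug price reference
#' code (396 = antidiabetic agents). Insulin products sit outside prefix 396
#' in that coding system, so they are identified by an explicit, configurable
#' code list; the default list holds representative insulin preparation codes
#' (price-reference group 2492).
#'
#' @param diagnosis_prefixes Character vector of ICD-10 prefixes.
#' @param medication_prefix Single drug-price-reference code prefix.
#' @param insulin_codes Character vector of exact insulin drug codes.
#' @return An object of class `code_set`.
#' @export
code_set <- function(diagnosis_prefixes = c("E11", "E12", "E13", "E14"),
                     medication_prefix = "396",
                     insulin_codes = default_insulin_codes()) {
  if (!length(diagnosis_prefixes) || any(!nzchar(diagnosis_prefixes))) {
    stop("`diagnosis_prefixes` must be non-empty strings")
  }
  if (length(medication_prefix) != 1L || !nzchar(medication_prefix)) {
    stop("`medication_prefix` must be a single non-empty string")
  }
  structure(
    list(diagnosis_prefixes = as.character(diagnosis_prefixes),
         medication_prefix = as.character(medication_prefix),
         insulin_codes = as.character(insulin_codes)),
    class = "code_set"
  )
}

#' Default insulin drug-price-reference codes
#'
#' A representative list of insulin preparation codes (group 2492 of the
#' Japanese drug price reference). Real analyses should supply the insurer's
#' full list via [code_set()].
#' @return Character vector of drug codes.
#' @export
default_insulin_codes <- function() {
  c("2492402G1022", "2492402G2029", "2492407G1021",
    "2492413G1020", "2492415G1024", "2492419G1022")
}

validate_claims <- function(claims) {
  req <- c("person_id", "fiscal_year", "record_type", "code", "suspected")
  miss <- setdiff(req, names(claims))
  if (length(miss)) stop("claims table is missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(claims$record_type), c("diagnosis", "prescription"))
  if (length(bad)) stop("unknown record_type value(s): ",
                        paste(bad, collapse = ", "))
  invisible(claims)
}

starts_with_any <- function(x, prefixes) {
  out <- rep(FALSE, length(x))
  for (p in prefixes) out <- out | startsWith(x, p)
  out
}

# person x fiscal-year logical matrix from a claim-line subset
flags_from_claims <- function(claims, persons, window) {
  m <- matrix(FALSE, nrow = length(persons), ncol = window$n_years,
              dimnames = list(persons, as.character(window$fys)))
  keep <- claims$person_id %in% persons & claims$fiscal_year %in% window$fys
  cl <- claims[keep, , drop = FALSE]
  if (nrow(cl)) {
    m[cbind(match(cl$person_id, persons),
            match(cl$fiscal_year, window$fys))] <- TRUE
  }
  attr(m, "n_ignored") <- sum(!keep)
  m
}

#' Raw per-year diagnosis flags from claims
#'
#' A cell is `TRUE` when the person has at least one non-suspected diagnosis
#' claim whose code starts with one of the configured ICD-10 prefixes in that
#' fiscal year. Suspected ("rule-out") diagnoses never count, and
#' prescription records never set diagnosis flags. Claims outside the window
#' or from persons outside `persons` are ignored (their number is returned in
#' the `"n_ignored"` attribute for run logs).
#'
#' @param claims Tibble of claim lines: `person_id`, `fiscal_year` (integer),
#'   `record_type` (`diagnosis`/`prescription`), `code`, `suspected` (0/1).
#' @param codes A [code_set()].
#' @param window A [study_window()].
#' @param persons Character vector defining the matrix rows (e.g. the cohort's
#'   person ids). Defaults to all persons appearing in `claims`.
#' @return Logical matrix, persons x fiscal years, with attribute
#'   `"n_ignored"`.
#' @export
yearly_diagnosis_flags <- function(claims, codes = code_set(), window,
                                   persons = sort(unique(claims$person_id))) {
  stopifnot(inherits(codes, "code_set"), inherits(window, "study_window"))
  validate_claims(claims)
  hit <- claims$record_type == "diagnosis" &
    !as.logical(claims$suspected) &
    starts_with_any(claims$code, codes$diagnosis_prefixes)
  flags_from_claims(claims[hit, , drop = FALSE], persons, window)
}

#' Carry disease status forward (monotone ever-diagnosed status)
#'
#' Once a person has ever been flagged, their status stays positive in all
#' later years: the disease is treated as incurable, so a year without a
#' diagnosis claim after a diagnosed year still counts as diagnosed (the
#' raw pattern no/yes/no becomes no/yes/yes). Idempotent.
#'
#' @param raw Logical matrix of raw per-year flags (persons x ordered fiscal
#'   years), as from [yearly_diagnosis_flags()].
#' @return Logical matrix of the same shape, monotone non-decreasing along
#'   each row.
#' @export
#' @examples
#' carry_forward(matrix(c(FALSE, TRUE, FALSE), nrow = 1))
carry_forward <- function(raw) {
  if (!is.matrix(raw) || !is.logical(raw)) stop("`raw` must be a logical matrix")
  if (ncol(raw) == 0L || nrow(raw) == 0L) return(raw)
  out <- raw
  for (j in seq_len(ncol(out))[-1L]) {
    out[, j] <- out[, j] | out[, j - 1L]
  }
  out
}

#' Per-year treatment-utilization flags from prescription claims
#'
#' Medication use: at least one prescription claim in the fiscal year whose
#' code starts with the medication prefix (default "396"). Insulin use: at
#' least one prescription claim whose code is in the configured insulin code
#' list. Utilization is a yearly measure — no carry-forward is applied, so a
#' person can be a user in one year and not the next.
#'
#' @inheritParams yearly_diagnosis_flags
#' @param kind `"medication"` or `"insulin"`.
#' @return Logical matrix, persons x fiscal years.
#' @export
utilization_flags <- function(claims, codes = code_set(), window,
                              kind = c("medication", "insulin"),
                              persons = sort(unique(claims$person_id))) {
  stopifnot(inherits(codes, "code_set"), inherits(window, "study_window"))
  kind <- match.arg(kind)
  validate_claims(claims)
  rx <- claims$record_type == "prescription"
  hit <- if (kind == "medication") {
    rx & startsWith(claims$code, codes$medication_prefix)
  } else {
    if (!length(codes$insulin_codes)) {
      stop("insulin ascertainment requires a non-empty `insulin_codes` list")
    }
    rx & claims$code %in% codes$insulin_codes
  }
  flags_from_claims(claims[hit, , drop = FALSE], persons, window)
}

#' Tidy per-person, per-year ascertainment status
#'
#' Convenience wrapper combining carried-forward disease status with yearly
#' medication and insulin utilization for a fixed person set.
#'
#' @inheritParams yearly_diagnosis_flags
#' @param persons Character vector of person ids (typically
#'   `cohort$person_id`).
#' @return Tibble: `person_id`, `fiscal_year`, `dm_status`, `med_use`,
#'   `insulin_use` (logicals).
#' @export
ascertain_status <- function(claims, codes = code_set(), window, persons) {
  dm <- carry_forward(yearly_diagnosis_flags(claims, codes, window, persons))
  med <- utilization_flags(claims, codes, window, "medication", persons)
  ins <- utilization_flags(claims, codes, window, "insulin", persons)
  tibble::tibble(
    person_id = rep(persons, times = window$n_years),
    fiscal_year = rep(window$fys, each = length(persons)),
    dm_status = as.vector(dm),
    med_use = as.vector(med),
    insulin_use = as.vector(ins)
  )
}
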