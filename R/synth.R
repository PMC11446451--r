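#' Default age-sex stratum structure for the simulator
#'
#' One row per sex x 5-year age band (ages 40+), calibrated to the reference
#' municipal cohort: stratum weights proportional to the published fixed
#' denominators, baseline ever-diagnosed prevalence from the baseline-year
#' column, and per-stratum annual increase equal to the published incidence
#' slope of each stratum's cumulative prevalence series.
#'
#' @return Tibble: `sex`, `age_band`, `weight`, `baseline_prevalence`,
#'   `annual_increase`.
#' @export
default_strata <- function() {
  counts <- table2_replica()
  slopes <- incidence_table(series_from_counts(counts))
  tab <- dplyr::left_join(counts, slopes, by = c("sex", "age_band", "n"))
  tibble::tibble(
    sex = tab$sex,
    age_band = tab$age_band,
    weight = tab$n / sum(tab$n),
    baseline_prevalence = tab$fy2015 / tab$n,
    annual_increase = tab$slope
  )
}

check_prob <- function(x, field, len = NULL) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("`", field, "` must be probability(ies) in [0, 1]")
  }
  if (!is.null(len) && !(length(x) %in% c(1L, len))) {
    stop("`", field, "` must have length 1 or ", len)
  }
  invisible(x)
}

#' Simulation configuration for the synthetic claims-and-ledger generator
#'
#' Defines the study conditions the generator emulates. Defaults reproduce
#' the reference analysis setting: a five-year window from FY2015, 24 age-sex
#' strata calibrated to the published cohort (see [default_strata()]),
#' roughly 10% of insured persons using no healthcare while undiagnosed,
#' modest annual disenrollment (migration) and mortality, occasional
#' suspected-only diabetes claims, and medication/insulin claim rates per
#' diagnosed person-year chosen so overall utilization sits near the
#' published per-FY shares (medication at about 46% of prevalence, insulin at
#' about 8%).
#'
#' @param n_persons Number of insured persons to simulate.
#' @param baseline_fy First fiscal year of the window.
#' @param n_years Window length in fiscal years (>= 2).
#' @param age_sex_strata Tibble with `sex`, `age_band`, `weight`,
#'   `baseline_prevalence`, `annual_increase` (weights sum to 1).
#' @param annual_death_prob Per person-year death probability; scalar or one
#'   value per stratum.
#' @param annual_leave_prob Per person-year disenrollment (migration)
#'   probability.
#' @param no_use_fraction Probability a person generates no claims at all
#'   while undiagnosed.
#' @param suspected_claim_rate Per person-year probability of a suspected
#'   ("rule-out") diabetes diagnosis claim among healthcare users.
#' @param medication_prob_given_case Per diagnosed person-year probability of
#'   an antidiabetic (prefix-396) prescription claim.
#' @param insulin_prob_given_case Per diagnosed person-year probability of an
#'   insulin prescription claim.
#' @param claim_emission_prob Probability a prevalent case emits a diabetes
#'   diagnosis claim in each year after the onset year (the onset year always
#'   emits). Lowering this exercises the carry-forward algorithm's
#'   insensitivity to intermittent coding.
#' @param seed Integer RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @return Validated object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 60000L,
                       baseline_fy = 2015L,
                       n_years = 5L,
                       age_sex_strata = default_strata(),
                       annual_death_prob = 0.02,
                       annual_leave_prob = 0.05,
                       no_use_fraction = 0.10,
                       suspected_claim_rate = 0.02,
                       medication_prob_given_case = 0.46,
                       insulin_prob_given_case = 0.08,
                       claim_emission_prob = 1.0,
                       seed = 1L) {
  n_persons <- as.integer(n_persons)
  if (is.na(n_persons) || n_persons < 1L) stop("`n_persons` must be a positive integer")
  n_years <- as.integer(n_years)
  if (is.na(n_years) || n_years < 2L) stop("`n_years` must be an integer >= 2")

  s <- age_sex_strata
  req <- c("sex", "age_band", "weight", "baseline_prevalence", "annual_increase")
  miss <- setdiff(req, names(s))
  if (length(miss)) stop("`age_sex_strata` is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (abs(sum(s$weight) - 1) > 1e-9) stop("`age_sex_strata` weights must sum to 1")
  check_prob(s$baseline_prevalence, "baseline_prevalence")
  check_prob(s$annual_increase, "annual_increase")
  if (any(s$baseline_prevalence + n_years * s$annual_increase > 1)) {
    stop("`age_sex_strata`: baseline_prevalence + n_years * annual_increase exceeds 1")
  }
  check_prob(annual_death_prob, "annual_death_prob", nrow(s))
  check_prob(annual_leave_prob, "annual_leave_prob")
  check_prob(no_use_fraction, "no_use_fraction")
  check_prob(suspected_claim_rate, "suspected_claim_rate")
  check_prob(medication_prob_given_case, "medication_prob_given_case")
  check_prob(insulin_prob_given_case, "insulin_prob_given_case")
  check_prob(claim_emission_prob, "claim_emission_prob")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer")

  structure(
    list(n_persons = n_persons, baseline_fy = as.integer(baseline_fy),
         n_years = n_years, age_sex_strata = s,
         annual_death_prob = rep_len(annual_death_prob, nrow(s)),
         annual_leave_prob = annual_leave_prob,
         no_use_fraction = no_use_fraction,
         suspected_claim_rate = suspected_claim_rate,
         medication_prob_given_case = medication_prob_given_case,
         insulin_prob_given_case = insulin_prob_given_case,
         claim_emission_prob = claim_emission_prob,
         seed = seed),
    class = "sim_config"
  )
}

# integer age sampled uniformly within a 5-year band ("95-" spans 95-99)
sample_age_in_band <- function(bands) {
  lo <- ifelse(bands == "95-", 95L, as.integer(sub("-.*", "", bands)))
  lo + sample.int(5L, length(bands), replace = TRUE) - 1L
}

dx_codes <- c("E11.9", "E11.6", "E11.2", "E13.9", "E14.9")
dx_weights <- c(0.6, 0.1, 0.1, 0.1, 0.1)
med_codes <- c("3961007F1025", "3962002F1028", "3969010F1023", "3969400F1022")
generic_codes <- c("I10", "J06.9", "M54.5", "K21.0")

#' Generate a synthetic insured population with ledger, claims and truth
#'
#' Simulates the administrative data the pipeline consumes. Each person gets
#' one enrollment spell starting at the window's first month; per person-year
#' they may die (ending the spell with reason `death`) or disenroll (reason
#' `disenrollment`); otherwise the spell runs to the window's end. Disease
#' onset is irreversible: per enrolled, alive, not-yet-diagnosed person-year
#' the onset hazard is `annual_increase / (1 - expected current prevalence)`,
#' so the expected annual increment in the ever-diagnosed share of the
#' baseline cohort equals the stratum's `annual_increase` — the simulator
#' parameterizes the estimand (the prevalence increment) directly rather
#' than the at-risk hazard. Diagnosed persons emit a non-suspected diabetes
#' diagnosis claim in the onset year and, with `claim_emission_prob`, in each
#' later enrolled year, plus medication/insulin prescription claims at the
#' configured rates. Healthcare users among the undiagnosed emit generic
#' (non-diabetes) claims and occasionally suspected-only diabetes claims; a
#' `no_use_fraction` share of persons emit no claims while undiagnosed.
#'
#' @param config A [sim_config()].
#' @return List of three tibbles: `ledger` (one spell per person), `claims`
#'   (one row per claim line), `truth` (per-person ground truth: stratum,
#'   `onset_fy`, `death_fy`, `leave_fy`, `no_use`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_persons
  strata <- config$age_sex_strata
  fy0 <- config$baseline_fy
  ny <- config$n_years

  sidx <- sample.int(nrow(strata), n, replace = TRUE, prob = strata$weight)
  person_id <- sprintf("P%06d", seq_len(n))
  sex <- strata$sex[sidx]
  band <- strata$age_band[sidx]
  age <- sample_age_in_band(band)
  no_use <- stats::runif(n) < config$no_use_fraction

  p0 <- strata$baseline_prevalence[sidx]
  delta <- strata$annual_increase[sidx]
  p_death <- config$annual_death_prob[sidx]

  onset_fy <- rep(NA_integer_, n)
  death_fy <- rep(NA_integer_, n)
  leave_fy <- rep(NA_integer_, n)
  end_month <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  enrolled <- rep(TRUE, n)

  # Phase 1 — truth process. Each year consumes a fixed number of RNG draws
  # (onset, death, leave, end months), so the realized truth is identical
  # across claim-emission settings under the same seed: the emission knob
  # changes coding behaviour, never the disease process.
  for (y in seq_len(ny) - 1L) {
    fy <- fy0 + y
    active <- alive & enrolled  # enrolled at the start of year y

    # onset: baseline prevalence draw in year 0, hazard draws thereafter;
    # the hazard targets the expected prevalence increment of the baseline
    # cohort, the analysis estimand
    at_risk <- active & is.na(onset_fy)
    p_onset <- if (y == 0L) p0 else delta / (1 - (p0 + (y - 1L) * delta))
    hit <- at_risk & stats::runif(n) < p_onset
    onset_fy[hit] <- fy

    # end-of-year events: death, then disenrollment among survivors
    dies <- active & stats::runif(n) < p_death
    death_fy[dies] <- fy
    alive[dies] <- FALSE
    leaves <- active & !dies & stats::runif(n) < config$annual_leave_prob
    leave_fy[leaves] <- fy
    enrolled[leaves] <- FALSE
    ended <- dies | leaves
    # spell ends in a uniformly chosen month of that fiscal year (Apr-Mar)
    end_month[ended] <- ym_index(sprintf("%d-04", fy)) +
      sample.int(12L, sum(ended), replace = TRUE) - 1L
  }

  # Phase 2 — claim emission given the truth. Persons who die or leave in a
  # year are covered for part of it and still emit that year's claims.
  claims_parts <- vector("list", ny)
  for (y in seq_len(ny) - 1L) {
    fy <- fy0 + y
    active <- (is.na(death_fy) | death_fy >= fy) &
      (is.na(leave_fy) | leave_fy >= fy)
    case <- active & !is.na(onset_fy) & onset_fy <= fy
    emit_dx <- case & (onset_fy == fy |
                         stats::runif(n) < config$claim_emission_prob)
    emit_med <- case & stats::runif(n) < config$medication_prob_given_case
    emit_ins <- case & stats::runif(n) < config$insulin_prob_given_case
    user <- active & !no_use
    emit_generic <- user & !case
    emit_susp <- user & stats::runif(n) < config$suspected_claim_rate

    claims_parts[[y + 1L]] <- dplyr::bind_rows(
      tibble::tibble(person_id = person_id[emit_dx], fiscal_year = fy,
                     record_type = "diagnosis",
                     code = sample(dx_codes, sum(emit_dx), TRUE, dx_weights),
                     suspected = 0L),
      tibble::tibble(person_id = person_id[emit_med], fiscal_year = fy,
                     record_type = "prescription",
                     code = sample(med_codes, sum(emit_med), TRUE),
                     suspected = 0L),
      tibble::tibble(person_id = person_id[emit_ins], fiscal_year = fy,
                     record_type = "prescription",
                     code = sample(default_insulin_codes(), sum(emit_ins), TRUE),
                     suspected = 0L),
      tibble::tibble(person_id = person_id[emit_generic], fiscal_year = fy,
                     record_type = "diagnosis",
                     code = sample(generic_codes, sum(emit_generic), TRUE),
                     suspected = 0L),
      tibble::tibble(person_id = person_id[emit_susp], fiscal_year = fy,
                     record_type = "diagnosis", code = "E11.9", suspected = 1L)
    )
  }

  window_end <- ym_index(sprintf("%d-03", fy0 + ny))
  end_reason <- ifelse(!is.na(death_fy), "death",
                       ifelse(!is.na(leave_fy), "disenrollment", "study_end"))
  spell_end <- ifelse(is.na(end_month), window_end, end_month)

  ledger <- tibble::tibble(
    person_id = person_id, sex = sex, age_at_baseline = age,
    spell_start = sprintf("%d-04", fy0),
    spell_end = ym_label(spell_end),
    end_reason = end_reason
  )
  claims <- dplyr::bind_rows(claims_parts)
  claims <- dplyr::arrange(claims, .data$person_id, .data$fiscal_year,
                           .data$record_type, .data$code, .data$suspected)
  truth <- tibble::tibble(
    person_id = person_id, sex = sex, age_band = band,
    onset_fy = onset_fy, death_fy = death_fy, leave_fy = leave_fy,
    no_use = no_use
  )
  list(ledger = ledger, claims = claims, truth = truth)
}

#' Write a simulated population to CSV files
#'
#' @param pop List from [generate_population()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`ledger.csv`, `claims.csv`,
#'   `truth.csv`; missing values written as empty strings).
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("ledger.csv", "claims.csv", "truth.csv"))
  readr::write_csv(pop$ledger, paths[1], na = "")
  readr::write_csv(pop$claims, paths[2], na = "")
  readr::write_csv(pop$truth, paths[3], na = "")
  invisible(paths)
}

#' Read a ledger CSV
#' @param path File path.
#' @return Ledger tibble (see [build_cohort()] for the schema).
#' @export
read_ledger <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    person_id = readr::col_character(), sex = readr::col_character(),
    age_at_baseline = readr::col_integer(),
    spell_start = readr::col_character(), spell_end = readr::col_character(),
    end_reason = readr::col_character()
  ))
}

#' Read a claims CSV
#' @param path File path.
#' @return Claims tibble (see [yearly_diagnosis_flags()] for the schema).
#' @export
read_claims <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    person_id = readr::col_character(),
    fiscal_year = readr::col_integer(),
    record_type = readr::col_character(),
    code = readr::col_character(),
    suspected = readr::col_integer()
  ))
}

#' Write the hand-built test fixture suite
#'
#' Writes a six-person ledger/claims pair exercising every continuity and
#' ascertainment edge in one small file pair — the carry-forward worked
#' example (diagnosis claims only in the second study year), a mover
#' (disenrollment mid-window), a gap person (re-enrollment after a hole in
#' coverage), a decedent with diabetes (retained, fixed denominator), a
#' suspected-only person (never a case), and a no-use person (zero claims) —
#' plus a copy of the published stratum-count replica table.
#'
#' @param outdir Output directory (created if missing).
#' @return Tibble manifest: `file`, `description`.
#' @export
write_fixture_suite <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  ledger <- tibble::tibble(
    person_id = c("P1", "P2", "P3a", "P3b", "P4", "P5", "P6"),
    sex = c("M", "F", "M", "M", "F", "M", "F"),
    age_at_baseline = c(63L, 45L, 72L, 72L, 80L, 50L, 67L),
    spell_start = c("2015-04", "2015-04", "2015-04", "2016-06", "2015-04",
                    "2015-04", "2015-04"),
    spell_end = c("2020-03", "2017-09", "2016-03", "2020-03", "2017-09",
                  "2020-03", "2020-03"),
    end_reason = c("study_end", "disenrollment", "disenrollment", "study_end",
                   "death", "study_end", "study_end")
  )
  ledger$person_id <- sub("[ab]$", "", ledger$person_id)

  claims <- dplyr::bind_rows(
    # P1: the carry-forward worked example (63-year-old, diagnosis FY2016
    # only -> status no, yes, yes, ...); non-monotone medication use
    tibble::tibble(person_id = "P1", fiscal_year = 2015:2019,
                   record_type = "diagnosis", code = "I10", suspected = 0L),
    tibble::tibble(person_id = "P1", fiscal_year = 2016L,
                   record_type = "diagnosis", code = "E11.9", suspected = 0L),
    tibble::tibble(person_id = "P1", fiscal_year = c(2016L, 2018L),
                   record_type = "prescription", code = "3961007F1025",
                   suspected = 0L),
    # P2: mover (excluded)
    tibble::tibble(person_id = "P2", fiscal_year = 2015L,
                   record_type = "diagnosis", code = "I10", suspected = 0L),
    # P3: gap person (excluded)
    tibble::tibble(person_id = "P3", fiscal_year = c(2015L, 2017L),
                   record_type = "diagnosis", code = "J06.9", suspected = 0L),
    # P4: diabetic decedent (retained; status carried past death)
    tibble::tibble(person_id = "P4", fiscal_year = 2015L,
                   record_type = "diagnosis", code = "E11.9", suspected = 0L),
    tibble::tibble(person_id = "P4", fiscal_year = 2015L,
                   record_type = "prescription", code = "2492402G1022",
                   suspected = 0L),
    tibble::tibble(person_id = "P4", fiscal_year = 2015:2017,
                   record_type = "prescription", code = "3969010F1023",
                   suspected = 0L),
    # P5: suspected-only diagnoses (never a case)
    tibble::tibble(person_id = "P5", fiscal_year = 2015:2019,
                   record_type = "diagnosis", code = "K21.0", suspected = 0L),
    tibble::tibble(person_id = "P5", fiscal_year = c(2015L, 2017L),
                   record_type = "diagnosis", code = "E11.9", suspected = 1L)
    # P6: no healthcare use at all (zero claim lines)
  )

  paths <- file.path(outdir, c("fixture_ledger.csv", "fixture_claims.csv",
                               "table2_replica.csv"))
  readr::write_csv(ledger, paths[1], na = "")
  readr::write_csv(claims, paths[2], na = "")
  readr::write_csv(table2_replica(), paths[3], na = "")

  tibble::tibble(
    file = basename(paths),
    description = c(
      "6-person ledger: worked example, mover, gap, decedent, suspected-only, no-use",
      "claim lines for the 6-person ledger (the no-use person has none)",
      "published stratum-count replica (24 strata x 5 fiscal years)"
    )
  )
}
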