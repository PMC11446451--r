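test_that("fiscal-year month arithmetic round-trips and assigns FY correctly", {
  ym <- c("2015-04", "2016-03", "2016-04", "2020-03")
  expect_identical(ym_label(ym_index(ym)), ym)
  expect_identical(fy_of_month(ym), c(2015L, 2015L, 2016L, 2019L))
  expect_error(ym_index("2015-13"), "malformed")
  expect_error(ym_index("201504"), "malformed")
})

test_that("age bands are frozen 5-year baseline bands with open top", {
  expect_identical(assign_age_band(63), "60-64")
  expect_identical(assign_age_band(c(40, 44, 45)), c("40-44", "40-44", "45-49"))
  expect_identical(assign_age_band(c(94, 95, 97, 104)),
                   c("90-94", "95-", "95-", "95-"))
  expect_identical(assign_age_band(39), "under-40")
  expect_error(assign_age_band(-1), "non-negative")
})

test_that("continuity classification covers every status exclusively", {
  w <- study_window(2015, 5)
  spell <- function(s, e, r) data.frame(spell_start = s, spell_end = e,
                                        end_reason = r)
  expect_identical(assess_continuity(spell("2015-04", "2020-03", "study_end"), w),
                   "continuous")
  expect_identical(assess_continuity(spell("2015-04", "2017-09", "death"), w),
                   "died_during")
  expect_identical(assess_continuity(spell("2015-04", "2017-09", "disenrollment"), w),
                   "left")
  expect_identical(
    assess_continuity(rbind(spell("2015-04", "2016-03", "disenrollment"),
                            spell("2016-06", "2020-03", "study_end")), w),
    "gap")
  expect_identical(assess_continuity(spell("2015-05", "2020-03", "study_end"), w),
                   "late_entry")
  # death in the window's final month is still an in-window death
  expect_identical(assess_continuity(spell("2015-04", "2020-03", "death"), w),
                   "died_during")
  # coverage truncated without a death is exclusion regardless of reason label
  expect_identical(assess_continuity(spell("2015-04", "2019-12", "study_end"), w),
                   "left")
  expect_error(
    assess_continuity(rbind(spell("2015-04", "2017-03", "disenrollment"),
                            spell("2016-06", "2020-03", "study_end")), w),
    "overlapping")
})

test_that("build_cohort keeps continuous + deceased, drops movers/gaps/under-40", {
  w <- study_window(2015, 5)
  cohort <- build_cohort(fixture_ledger(), w)

  expect_setequal(cohort$person_id, c("P1", "P4", "P5", "P6"))
  expect_false(any(c("P2", "P3") %in% cohort$person_id))

  counts <- attr(cohort, "continuity_counts")
  expect_identical(counts[["left"]], 1L)       # the mover
  expect_identical(counts[["gap"]], 1L)        # the re-enroller
  expect_identical(counts[["died_during"]], 1L)

  p4 <- cohort[cohort$person_id == "P4", ]
  expect_identical(p4$death_fy, 2017L)
  expect_identical(cohort[cohort$person_id == "P1", ]$age_band, "60-64")

  under40 <- fixture_ledger()
  under40$age_at_baseline[under40$person_id == "P5"] <- 39L
  expect_false("P5" %in% build_cohort(under40, w)$person_id)
})

test_that("build_cohort rejects conflicting person attributes", {
  w <- study_window(2015, 5)
  bad <- fixture_ledger()
  bad$age_at_baseline[bad$person_id == "P3"][2] <- 70L
  expect_error(build_cohort(bad, w), "conflicting")
})

test_that("cohort recount matches simulator truth when nobody leaves", {
  cfg <- one_stratum_config(n = 2000L, death = 0.02, leave = 0, seed = 7L)
  pop <- generate_population(cfg)
  cohort <- build_cohort(pop$ledger, study_window(2015, 5))
  # no migration: everyone aged >= 40 is retained, deaths included
  expect_identical(nrow(cohort), nrow(pop$truth))
  expect_identical(sort(cohort$person_id[!is.na(cohort$death_fy)]),
                   sort(pop$truth$person_id[!is.na(pop$truth$death_fy)]))
})

test_that("open population counts persons per enrolled fiscal year", {
  w <- study_window(2015, 5)
  pop <- open_population(fixture_ledger(), w)
  # mover P2 covered in FY2015-2017 only; gap person P3 in all five FYs
  expect_identical(sort(pop$fiscal_year[pop$person_id == "P2"]), 2015:2017)
  expect_identical(sort(pop$fiscal_year[pop$person_id == "P3"]), 2015:2019)
  expect_identical(sort(pop$fiscal_year[pop$person_id == "P4"]), 2015:2017)
  expect_identical(sum(pop$fiscal_year == 2019), 4L) # P1, P3, P5, P6
})
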