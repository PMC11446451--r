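test_that("config validation names the offending field", {
  expect_error(sim_config(n_persons = 0), "n_persons")
  expect_error(sim_config(no_use_fraction = 1.2), "no_use_fraction")
  expect_error(sim_config(annual_leave_prob = -0.1), "annual_leave_prob")
  bad_w <- default_strata(); bad_w$weight <- bad_w$weight * 2
  expect_error(sim_config(age_sex_strata = bad_w), "sum to 1")
  sat <- tibble::tibble(sex = "M", age_band = "60-64", weight = 1,
                        baseline_prevalence = 0.9, annual_increase = 0.05)
  expect_error(sim_config(age_sex_strata = sat), "exceeds 1")
})

test_that("zero rates produce a disease-free population", {
  cfg <- one_stratum_config(n = 500L, p0 = 0, delta = 0, seed = 2L)
  pop <- generate_population(cfg)
  expect_true(all(is.na(pop$truth$onset_fy)))
  dm <- pop$claims$record_type == "diagnosis" & pop$claims$suspected == 0 &
    startsWith(pop$claims$code, "E1") & !startsWith(pop$claims$code, "E10")
  expect_identical(sum(dm), 0L)
})

test_that("identical config and seed give byte-identical CSV output", {
  cfg <- one_stratum_config(n = 300L, death = 0.02, leave = 0.05, seed = 9L)
  d1 <- file.path(tempdir(), "sim-a"); d2 <- file.path(tempdir(), "sim-b")
  p1 <- write_population(generate_population(cfg), d1)
  p2 <- write_population(generate_population(cfg), d2)
  for (i in seq_along(p1)) {
    expect_identical(readBin(p1[i], "raw", file.size(p1[i])),
                     readBin(p2[i], "raw", file.size(p2[i])))
  }
  # and a different seed changes the data
  cfg2 <- one_stratum_config(n = 300L, death = 0.02, leave = 0.05, seed = 10L)
  expect_false(identical(generate_population(cfg2)$truth$onset_fy,
                         generate_population(cfg)$truth$onset_fy))
})

test_that("truth is internally consistent and claims respect onset order", {
  cfg <- one_stratum_config(n = 3000L, death = 0.02, leave = 0.05, seed = 4L,
                            suspected_claim_rate = 0.05)
  pop <- generate_population(cfg)
  tr <- pop$truth
  expect_false(any(!is.na(tr$death_fy) & !is.na(tr$leave_fy)))
  expect_true(all(tr$onset_fy[!is.na(tr$onset_fy)] %in% 2015:2019))

  # no non-suspected diabetes diagnosis claim before the true onset year
  dm <- pop$claims[pop$claims$record_type == "diagnosis" &
                     pop$claims$suspected == 0 &
                     startsWith(pop$claims$code, "E1") &
                     !startsWith(pop$claims$code, "E10"), ]
  first_claim <- tapply(dm$fiscal_year, dm$person_id, min)
  onset <- tr$onset_fy[match(names(first_claim), tr$person_id)]
  expect_true(all(!is.na(onset)))
  expect_true(all(first_claim >= onset))
  # and every case emits in its onset year
  expect_true(all(first_claim == onset))

  # every person appears in the ledger even with zero claims
  expect_setequal(pop$ledger$person_id, tr$person_id)
  expect_gt(length(setdiff(tr$person_id, pop$claims$person_id)), 0)
})

test_that("realized no-use fraction matches the configured rate", {
  cfg <- one_stratum_config(n = 20000L, seed = 6L, death = 0.02, leave = 0.05)
  pop <- generate_population(cfg)
  tr <- pop$truth
  never_dx_survivor <- is.na(tr$onset_fy) & is.na(tr$death_fy) & is.na(tr$leave_fy)
  no_claims <- !(tr$person_id %in% pop$claims$person_id)
  frac <- mean(no_claims[never_dx_survivor])
  se <- sqrt(0.10 * 0.90 / sum(never_dx_survivor))
  expect_lt(abs(frac - 0.10), 3 * se)
})

test_that("realized annual increase in ever-diagnosed truth tracks the target", {
  cfg <- one_stratum_config(n = 20000L, seed = 8L)
  pop <- generate_population(cfg)
  tr <- pop$truth
  prev <- sapply(2015:2019, function(fy)
    mean(!is.na(tr$onset_fy) & tr$onset_fy <= fy))
  increments <- diff(prev)
  se <- sqrt(0.03 * 0.97 / nrow(tr))
  expect_true(all(abs(increments - 0.03) < 3 * se))
  # baseline prevalence close to its target too
  expect_lt(abs(prev[1] - 0.15), 3 * sqrt(0.15 * 0.85 / nrow(tr)))
})

test_that("fixture suite writes the documented files", {
  dir <- file.path(tempdir(), "fix2")
  man <- write_fixture_suite(dir)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_identical(nrow(table2_replica()), 24L)
  led <- read_ledger(file.path(dir, "fixture_ledger.csv"))
  expect_identical(length(unique(led$person_id)), 6L)
})
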