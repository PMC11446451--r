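w5 <- study_window(2015, 5)

test_that("incidence slope matches hand-checkable series", {
  # published stratum example: counts (67,86,108,129,149) over n = 1148
  s <- incidence_slope(c(67, 86, 108, 129, 149) / 1148)
  expect_equal(round_half_up(100 * s$slope, 2), 1.80)
  # second published stratum: male 60-64
  expect_equal(round_half_up(100 * incidence_slope(
    c(445, 594, 719, 823, 921) / 2559)$slope, 2), 4.62)
  # exact closed-form cases
  expect_equal(incidence_slope(rep(0.3, 5))$slope, 0)
  expect_equal(incidence_slope(0.02 * (0:4))$slope, 0.02, tolerance = 1e-15)
  expect_error(incidence_slope(0.5), "at least 2")
})

test_that("incidence slope agrees with the normal-equations oracle", {
  set.seed(99)
  for (i in 1:1000) {
    len <- sample(2:8, 1)
    n <- sample(50:5000, 1)
    counts <- sort(sample.int(n, len, replace = TRUE))
    y <- counts / n
    expect_equal(incidence_slope(y)$slope, oracle_slope(y), tolerance = 1e-12)
  }
})

test_that("cumulative series uses fixed denominators and retains decedents", {
  cohort <- build_cohort(fixture_ledger(), w5)
  status <- carry_forward(yearly_diagnosis_flags(
    fixture_claims(), code_set(), w5, cohort$person_id))
  series <- cumulative_prevalence_series(status, cohort)

  overall <- series[series$sex == "All", ]
  expect_identical(overall$n, rep(4L, 5))          # denominator never shrinks
  expect_identical(overall$count, c(1L, 2L, 2L, 2L, 2L))  # P4 then P1
  expect_equal(overall$proportion, c(.25, .5, .5, .5, .5))

  # the deceased P4 keeps status TRUE in years after death
  p4_stratum <- series[series$sex == "F" & series$age_band == "80-84", ]
  expect_identical(p4_stratum$count, rep(1L, 5))

  # non-decreasing within every stratum
  mono <- dplyr::summarise(
    dplyr::group_by(series, sex, age_band),
    ok = !is.unsorted(count[order(fiscal_year)]), .groups = "drop")
  expect_true(all(mono$ok))

  expect_error(cumulative_prevalence_series(status[-1, , drop = FALSE], cohort),
               "match the cohort")
})

test_that("series ingest from aggregate counts reproduces proportions", {
  series <- series_from_counts(table2_replica())
  expect_identical(nrow(series), 24L * 5L)
  m6064 <- series[series$sex == "M" & series$age_band == "60-64", ]
  expect_equal(round_half_up(100 * m6064$proportion, 1),
               c(17.4, 23.2, 28.1, 32.2, 36.0))
  bad <- table2_replica(); bad$fy2019[1] <- bad$n[1] + 1L
  expect_error(series_from_counts(bad), "exceeds")
})

test_that("pooled slope equals denominator-weighted mean of stratum slopes", {
  series <- series_from_counts(table2_replica())
  pooled <- pooled_slope(series)$slope
  strat <- incidence_table(series)
  expect_equal(pooled, sum(strat$n * strat$slope) / sum(strat$n),
               tolerance = 1e-10)

  # random small tables keep the identity
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    counts <- tibble::tibble(
      sex = rep("M", k), age_band = paste0("b", seq_len(k)),
      n = sample(100:2000, k))
    for (fy in 2015:2019) {
      counts[[paste0("fy", fy)]] <- sapply(counts$n, function(nn)
        sample.int(nn, 1))
    }
    ser <- series_from_counts(counts)
    st <- incidence_table(ser)
    expect_equal(pooled_slope(ser)$slope,
                 sum(st$n * st$slope) / sum(st$n), tolerance = 1e-10)
  }

  # single stratum: pooling is the identity
  one <- series[series$sex == "M" & series$age_band == "40-44", ]
  expect_equal(pooled_slope(one)$slope,
               incidence_slope(one$proportion)$slope)

  # two equal-n strata: pooled slope is the plain average
  eq <- tibble::tibble(sex = c("M", "F"), age_band = "60-64", n = 1000L,
                       fy2015 = c(100L, 200L), fy2016 = c(130L, 220L),
                       fy2017 = c(160L, 240L), fy2018 = c(190L, 260L),
                       fy2019 = c(220L, 280L))
  ser_eq <- series_from_counts(eq)
  st_eq <- incidence_table(ser_eq)
  expect_equal(pooled_slope(ser_eq)$slope, mean(st_eq$slope), tolerance = 1e-12)
})

test_that("weighted model's year coefficient is the weighted mean slope", {
  series <- series_from_counts(table2_replica())
  model <- fit_weighted_model(series)
  strat <- incidence_table(series)
  expect_equal(model$slope, sum(strat$n * strat$slope) / sum(strat$n),
               tolerance = 1e-10)
  expect_true(model$ci_low <= model$slope && model$slope <= model$ci_high)

  # affine recoding of the year labels leaves the coefficient unchanged
  shifted <- dplyr::mutate(series, fiscal_year = fiscal_year - 2015L)
  expect_equal(fit_weighted_model(shifted)$slope, model$slope,
               tolerance = 1e-12)

  # single stratum collapses to that stratum's OLS slope
  one <- series[series$sex == "F" & series$age_band == "95-", ]
  expect_equal(fit_weighted_model(one)$slope,
               incidence_slope(one$proportion)$slope, tolerance = 1e-12)

  # two strata with n1 = 3 n2: coefficient is (3 a + b) / 4
  two <- tibble::tibble(sex = c("M", "M"), age_band = c("40-44", "45-49"),
                        n = c(3000L, 1000L),
                        fy2015 = c(300L, 100L), fy2016 = c(390L, 140L),
                        fy2017 = c(480L, 170L), fy2018 = c(570L, 210L),
                        fy2019 = c(660L, 240L))
  ser2 <- series_from_counts(two)
  st2 <- incidence_table(ser2)
  expect_equal(fit_weighted_model(ser2)$slope,
               (3 * st2$slope[st2$age_band == "40-44"] +
                  st2$slope[st2$age_band == "45-49"]) / 4,
               tolerance = 1e-10)
})

test_that("per-FY open-population table counts raw flags per stratum", {
  pop <- open_population(fixture_ledger(), w5)
  pop_ids <- sort(unique(pop$person_id))
  claims <- fixture_claims()
  t1 <- annual_prevalence_table(pop, list(
    PR = yearly_diagnosis_flags(claims, code_set(), w5, pop_ids),
    MU = utilization_flags(claims, code_set(), w5, "medication", pop_ids),
    IU = utilization_flags(claims, code_set(), w5, "insulin", pop_ids)
  ))
  # P1 (M 60-64): raw diagnosis only in FY2016 -> PR drops back in FY2017
  pr_p1 <- t1[t1$sex == "M" & t1$age_band == "60-64" & t1$measure == "PR", ]
  expect_identical(pr_p1$cases, c(0L, 1L, 0L, 0L, 0L))
  expect_identical(pr_p1$n, rep(1L, 5))
  # P4 (F 80-84) leaves the open population after death in FY2017
  f80 <- t1[t1$sex == "F" & t1$age_band == "80-84", ]
  expect_identical(sort(unique(f80$fiscal_year)), 2015:2017)
  iu_p4 <- f80[f80$measure == "IU", ]
  expect_identical(iu_p4$cases, c(1L, 0L, 0L))
})
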