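# Published per-stratum annual incidence (% per year, 2 decimals), in the
# order of the replica table rows: Male 40-44 ... 95-, then Female.
printed_incidence <- c(
  1.80, 2.18, 3.07, 2.86, 4.62, 3.72, 3.38, 3.58, 3.03, 2.79, 2.22, 1.72,
  1.21, 1.84, 1.60, 2.43, 3.35, 3.19, 3.12, 3.41, 2.93, 2.64, 2.11, 1.40
)

# fixture suite written into a session-temp dir once per test run
fixture_dir <- local({
  dir <- file.path(tempdir(), "claimscohort-fixtures")
  if (!dir.exists(dir)) write_fixture_suite(dir)
  dir
})

fixture_ledger <- function() read_ledger(file.path(fixture_dir, "fixture_ledger.csv"))
fixture_claims <- function() read_claims(file.path(fixture_dir, "fixture_claims.csv"))

# one-stratum config for truth-recovery checks: the generator's own
# study-condition defaults scaled to a single stratum
one_stratum_config <- function(n = 20000L, p0 = 0.15, delta = 0.03, seed = 1L,
                               death = 0, leave = 0, ...) {
  sim_config(
    n_persons = n,
    age_sex_strata = tibble::tibble(
      sex = "M", age_band = "60-64", weight = 1,
      baseline_prevalence = p0, annual_increase = delta
    ),
    annual_death_prob = death, annual_leave_prob = leave,
    seed = seed, ...
  )
}

# independent slope oracle: brute-force normal equations, no closed form
oracle_slope <- function(y, x = seq_along(y) - 1) {
  X <- cbind(1, x)
  unname(solve(crossprod(X), crossprod(X, y))[2, 1])
}
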