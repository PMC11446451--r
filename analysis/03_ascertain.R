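#!/usr/bin/env Rscript
# Step 3 — claims-based case ascertainment for the fixed cohort.
#
# Non-suspected diagnosis claims with ICD-10 codes E11-E14 define yearly
# disease flags; carry-forward makes the ever-diagnosed status monotone
# (diabetes is treated as incurable). Prescription claims give yearly
# (non-monotone) medication (prefix 396) and insulin utilization flags.

suppressPackageStartupMessages(library(claimscohort))

cohort <- readr::read_csv("results/cohort.csv", show_col_types = FALSE)
claims <- read_claims("results/simulated/claims.csv")
window <- study_window(2015, 5)

status <- ascertain_status(claims, code_set(), window, cohort$person_id)
readr::write_csv(status, "results/status.csv")

message("ever-diagnosed cohort members by FY:")
for (fy in sort(unique(status$fiscal_year))) {
  message(sprintf("  FY%d: %d", fy,
                  sum(status$dm_status[status$fiscal_year == fy])))
}
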