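#!/usr/bin/env Rscript
# Compare per-patient crackle feature summaries between the groups:
# means +/- SD per group with Welch t-tests of IPF against CHF and PN,
# one row per feature and breath phase. Expects the tables written by
# 01_simulate_cohorts.R.

suppressPackageStartupMessages(library(cracklelab))

summaries <- read.csv("results/patient_summaries.csv")
cmp <- compare_groups(summaries)
write.csv(cmp, "results/group_comparison.csv", row.names = FALSE)
writeLines(comparison_markdown(cmp), "results/group_comparison.md")

sig <- cmp[cmp$sig_CHF & cmp$sig_PN, c("feature", "phase", "p_CHF", "p_PN")]
cat("Features separating IPF from both CHF and PN at p < .05:\n")
print(sig, row.names = FALSE)
cat("\nFull table in results/group_comparison.{csv,md}\n")
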