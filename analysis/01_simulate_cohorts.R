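#!/usr/bin/env Rscript
# Simulate three paired tumor/NAT survival-proteome cohorts sharing the same
# planted recurrence biology (different sampling seeds), and write them in
# the TSV dialect the pipeline ingests. Downstream scripts (02-04) consume
# these files; 05-06 simulate their own validation and treatment data.

suppressPackageStartupMessages(library(natrecur))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec_for <- function(seed) cohort_spec(
  n_patients = 150, n_proteins = 80,
  planted_sets = list(
    list(tissue = "tumor", direction = "unfavorable", size = 12,
         log_hr_per_sd = log(2.5)),
    list(tissue = "tumor", direction = "favorable", size = 12,
         log_hr_per_sd = log(2.5)),
    list(tissue = "nat", direction = "unfavorable", size = 12,
         log_hr_per_sd = log(2.5)),
    list(tissue = "nat", direction = "favorable", size = 12,
         log_hr_per_sd = log(2.5))),
  missing_fraction = 0.05, seed = seed)

for (i in 1:3) {
  co <- generate_cohort(spec_for(100 + i))
  stem <- file.path(out, sprintf("cohort%d", i))
  write_expression_matrix(co$tumor, paste0(stem, "_tumor.tsv"))
  write_expression_matrix(co$nat, paste0(stem, "_nat.tsv"))
  write_tsv(co$clinical, paste0(stem, "_clinical.tsv"))
  write_tsv(co$truth, paste0(stem, "_truth.tsv"))
  cat(sprintf(
    "cohort%d: %d patients, %d proteins, %.0f%% DFS events, %.1f%% cells missing\n",
    i, ncol(co$tumor), nrow(co$tumor), 100 * mean(co$clinical$dfs_event),
    100 * mean(is.na(co$tumor))))
}
cat("inputs written under", out, "\n")
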