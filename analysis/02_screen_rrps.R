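#!/usr/bin/env Rscript
# Screen recurrence-related proteins (RRPs) in every cohort and tissue,
# build the four direction sets per cohort, intersect them across cohorts,
# and apply the drug-target filter (unfavorable somewhere, never favorable).
# Reads the TSVs written by 01_simulate_cohorts.R.

suppressPackageStartupMessages(library(natrecur))

data_dir <- "results/data"
stopifnot(file.exists(file.path(data_dir, "cohort1_tumor.tsv")))

configs <- lapply(1:3, function(i) list(
  tumor = file.path(data_dir, sprintf("cohort%d_tumor.tsv", i)),
  nat = file.path(data_dir, sprintf("cohort%d_nat.tsv", i)),
  clinical = file.path(data_dir, sprintf("cohort%d_clinical.tsv", i)),
  cohort_id = sprintf("cohort%d", i),
  outdir = sprintf("results/cohort%d", i)))

res <- run_multicohort(configs, "results/consensus")

for (i in 1:3) {
  r <- res$per_cohort[[i]]
  cat(sprintf("cohort%d: %d tumor RRPs (%d unfavorable), %d NAT RRPs (%d unfavorable)\n",
              i, sum(r$rrp_tumor$significant),
              sum(r$rrp_tumor$significant & r$rrp_tumor$direction == "unfavorable"),
              sum(r$rrp_nat$significant),
              sum(r$rrp_nat$significant & r$rrp_nat$direction == "unfavorable")))
}
cat("consensus set sizes:",
    paste(sprintf("%s=%d", names(res$consensus_sets),
                  lengths(res$consensus_sets)), collapse = ", "), "\n")

truth <- utils::read.delim(file.path(data_dir, "cohort1_truth.tsv"))
planted_unf <- truth$protein_id[truth$direction == "unfavorable"]
cat(sprintf("target filter kept %d proteins; %.0f%% of planted unfavorable retained\n",
            length(res$targets),
            100 * mean(planted_unf %in% res$targets)))
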