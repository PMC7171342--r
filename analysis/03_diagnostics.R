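#!/usr/bin/env Rscript
# Step 3 — FLM classifier evaluation.
#
# Evaluates the L/S ratio classifier (cutoff 10.0) and the LBC classifier
# (cutoff 50 x 1e9/L) on the bundled 33-sample clinical cohort, and then
# the L/S classifier on the simulated cohort quantified in step 2.
# Premature is the positive class; 18-week controls count as premature.

suppressMessages(library(amniolipids))

rows <- list()
as_row <- function(label, r) {
  data.frame(cohort = label, method = r$method, cutoff = r$cutoff,
             tp = r$tp, fn = r$fn, tn = r$tn, fp = r$fp,
             sensitivity_pct = r$sensitivity, specificity_pct = r$specificity)
}

t1 <- clinical_cohort()
ls <- evaluate_classifier(t1, "ls", cutoff = 10.0)
lbc <- evaluate_classifier(t1, "lbc", cutoff = 50)
message("clinical cohort, L/S ratio:")
print(ls)
message("clinical cohort, LBC:")
print(lbc)
rows$clin_ls <- as_row("clinical", ls)
rows$clin_lbc <- as_row("clinical", lbc)

lib <- load_library("results/library.csv")
mat <- read_matrix("results/intensity_matrix.tsv")
records <- read_cohort("results/cohort_metadata.csv")
records <- records[match(rownames(mat), records$sample_id), ]
records$ls_ratio <- unname(ls_ratios(mat, lib))
write.csv(records, "results/cohort_with_ls.csv", row.names = FALSE)
sim_ls <- evaluate_classifier(records, "ls", cutoff = 10.0)
sim_lbc <- evaluate_classifier(records, "lbc", cutoff = 50)
message("simulated cohort, L/S ratio from extracted intensities:")
print(sim_ls)
rows$sim_ls <- as_row("simulated", sim_ls)
rows$sim_lbc <- as_row("simulated", sim_lbc)

perf <- do.call(rbind, rows)
write.table(perf, "results/diagnostic_performance.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote results/diagnostic_performance.tsv")
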