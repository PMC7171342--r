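#!/usr/bin/env Rscript
# Step 4 — biomarker discovery.
#
# Compares mature vs premature samples of the simulated cohort: Welch
# t-test p-value, mature/premature fold change of group means, and PLS-DA
# VIP score per species, then the selection rule p < 0.05, VIP > 1.1,
# FC > 2. With the default generator the lecithin rise is the real signal,
# so the selected species should be dominated by diacyl PCs.

suppressMessages(library(amniolipids))

lib <- load_library("results/library.csv")
mat <- read_matrix("results/intensity_matrix.tsv")
records <- read_cohort("results/cohort_metadata.csv")
records <- records[match(rownames(mat), records$sample_id), ]

two <- records$flm_outcome %in% c("premature", "mature")
tab <- biomarker_stats(mat[records$sample_id[two], ],
                       records$flm_outcome[two])
write.table(format(tab, digits = 6), "results/biomarker_table.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

sel <- select_biomarkers(tab)
write.table(format(sel, digits = 6), "results/biomarkers_selected.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

ann <- lib[match(sel$species_name, lib$name), ]
message(nrow(sel), " species pass the selection rule; ",
        sum(ann$is_lecithin), " are lecithins (diacyl PCs)")
message("top hits by fold change:")
print(head(sel[, c("species_name", "fold_change", "vip", "p_value")], 10),
      digits = 4)
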