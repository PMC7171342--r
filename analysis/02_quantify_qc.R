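#!/usr/bin/env Rscript
# Step 2 — targeted quantification and QC.
#
# Matches every peak list against the library (|ppm| <= 5, RT +/- 0.2 min),
# TIC-normalizes the intensity matrix, and assesses precision: per-class
# QC replicate CVs and the PCA overview in which the QC injections should
# form a tight cluster among the biological samples.

suppressMessages(library(amniolipids))

lib <- load_library("results/library.csv")
cohort_pl <- read_peaklists("results/cohort_peaklists.csv")
qc_pl <- read_peaklists("results/qc_peaklists.csv")

mat <- tic_normalize(build_matrix(cohort_pl, lib))
write_matrix(mat, "results/intensity_matrix.tsv")
message("intensity matrix: ", nrow(mat), " samples x ", ncol(mat), " species")

qc_mat <- tic_normalize(build_matrix(qc_pl, lib))
rep <- qc_cv(qc_mat, lib)
qc_tab <- data.frame(class = names(rep$class_average_cv),
                     average_cv_pct = round(unname(rep$class_average_cv), 2))
write.table(qc_tab, "results/qc_class_cv.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
message(sprintf("QC precision: PC-class average CV %.2f%%, SM %.2f%%",
                rep$class_average_cv[["PC"]], rep$sphingomyelin_average_cv))

pca <- pca_scores(tic_normalize(build_matrix(c(cohort_pl, qc_pl), lib)), 2)
scores <- data.frame(sample_id = rownames(pca$scores), round(pca$scores, 4),
                     is_qc = grepl("^QC", rownames(pca$scores)))
write.table(scores, "results/pca_scores.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
qc_spread <- apply(pca$scores[scores$is_qc, ], 2, sd)
all_spread <- apply(pca$scores, 2, sd)
message(sprintf(
  "PCA: PC1/PC2 explain %.0f%%/%.0f%% of variance; QC score sd is %.0f%%/%.0f%% of the overall sd",
  100 * pca$explained_variance[1], 100 * pca$explained_variance[2],
  100 * qc_spread[1] / all_spread[1], 100 * qc_spread[2] / all_spread[2]))
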