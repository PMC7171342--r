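#!/usr/bin/env Rscript
# Step 1 — simulate the study inputs.
#
# Generates the targeted 151-lipid library, a gestational-age-structured
# cohort of amniotic-fluid peak lists (18-week controls, premature,
# preterm-mature and term-mature groups), and six QC replicate injections
# of a pooled sample. Everything downstream (02-05) reads these files.

suppressMessages(library(amniolipids))

seed <- 20240101L
out <- "results"
dir.create(out, showWarnings = FALSE)

lib <- generate_library(seed)
save_library(lib, file.path(out, "library.csv"))
message("library: ", nrow(lib), " species (",
        paste(sprintf("%s=%d", names(counts_by_class(lib))[1:4],
                      counts_by_class(lib)[1:4]), collapse = ", "),
        "); ", sum(lib$is_lecithin), " lecithins, ",
        sum(lib$is_sphingomyelin), " sphingomyelins")

cohort <- generate_cohort(cohort_spec(n_per_group = 10, seed = seed), lib)
write_peaklists(cohort$peaklists, file.path(out, "cohort_peaklists.csv"))
write.csv(cohort$records, file.path(out, "cohort_metadata.csv"),
          row.names = FALSE)
message("cohort: ", nrow(cohort$records), " samples (",
        paste(names(table(cohort$records$group)),
              table(cohort$records$group), sep = "=", collapse = ", "), ")")

qc <- generate_qc(lib, n_reps = 6, seed = seed + 1L)
write_peaklists(qc, file.path(out, "qc_peaklists.csv"))
message("QC: ", length(qc), " replicate injections")

write_pathways(generate_toy_pathways(), file.path(out, "toy_pathways.json"))
message("wrote toy pathway bundle")
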