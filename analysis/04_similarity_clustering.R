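#!/usr/bin/env Rscript
# Stage 4: similarity search and two-pass SOM clustering.
#
# Removes profiles with more than two positive cytotoxicity endpoints,
# searches the reference database by Pearson correlation (top 10 above
# r = 0.6), and clusters profiles with the SOM twice: all profiles on a
# 7x7 grid, then the cytotoxicity-filtered set on a 6x6 grid.

suppressPackageStartupMessages(library(phenotox))

data_dir <- "results/data"
out <- "results"
pm <- read_profile_matrix(file.path(out, "profiles.tsv"))
counts <- utils::read.csv(file.path(out, "cytotox_counts.csv"),
                          stringsAsFactors = FALSE)
ref_raw <- utils::read.table(file.path(data_dir, "reference_db.tsv"),
                             sep = "\t", header = TRUE, check.names = FALSE, comment.char = "",
                             stringsAsFactors = FALSE)
meta <- c("label", "mechanism", "concentration", "n_cytotox")
db <- reference_db(as.matrix(ref_raw[, setdiff(names(ref_raw), meta)]),
                   ref_raw$label, ref_raw$concentration, ref_raw$n_cytotox,
                   ref_raw$mechanism)
cfg <- pipeline_config()

pm_filtered <- filter_for_profiling(pm, counts,
                                    cfg$max_cytotox_endpoints_for_profiling)
matches <- similarity_table(pm_filtered, db, cfg)
som <- two_pass_clustering(pm, counts, cfg)

utils::write.csv(matches, file.path(out, "similarity.csv"), row.names = FALSE)
utils::write.csv(som$full$assignments, file.path(out, "som_full_assignments.csv"),
                 row.names = FALSE)
utils::write.csv(som$filtered$assignments,
                 file.path(out, "som_filtered_assignments.csv"),
                 row.names = FALSE)
utils::write.csv(som$filtered$cluster_summary,
                 file.path(out, "som_cluster_summary.csv"), row.names = FALSE)
utils::write.table(som$filtered$model$codebook,
                   file.path(out, "som_codebook.tsv"), sep = "\t",
                   row.names = FALSE)

cat(sprintf("Cytotoxicity filter removed %d of %d profiles\n",
            nrow(pm) - nrow(pm_filtered), nrow(pm)))
cat(sprintf("Similarity matches above r = %.1f: %d (for %d query profiles)\n",
            cfg$similarity_r_min, nrow(matches),
            length(unique(paste(matches$sample_id, matches$concentration)))))
cat(sprintf("SOM pass 1: 7x7 grid, final quantization error %.4f\n",
            tail(som$full$model$qe, 1)))
cat(sprintf("SOM pass 2: 6x6 grid on %d profiles, final quantization error %.4f\n",
            nrow(som$filtered$assignments), tail(som$filtered$model$qe, 1)))
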