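#!/usr/bin/env Rscript
# Stage 5: assay quality acceptance.
#
# Computes per-plate vehicle %CV (aggregated as the max across endpoints on
# a plate), establishes the 1% false-negative Pearson cutoff from a
# positive-control reference set, and applies the acceptance rule: the
# positive control passes the Pearson test and at least 95% of plates have
# %CV < 20.

suppressPackageStartupMessages(library(phenotox))

data_dir <- "results/data"
out <- "results"
vocab <- read_endpoint_vocabulary(file.path(data_dir, "endpoints.csv"))
wells <- read_well_table(file.path(data_dir, "wells.csv"), vocab)

cvs <- plate_cv_table(wells)
reference <- simulate_positive_controls(vocab, 1000, noise_sd = 0.05,
                                        seed = 20260930L)
new_pc <- simulate_positive_controls(vocab, 1, noise_sd = 0.05,
                                     seed = 20260931L)[1, ]
qc <- qc_accept(new_pc, reference, cvs$cv_percent)

utils::write.csv(cvs, file.path(out, "qc_plate_cv.csv"), row.names = FALSE)
utils::write.csv(data.frame(
  pearson_r = qc$pearson_r, cutoff_r = qc$cutoff_r,
  pearson_pass = qc$pearson_pass,
  plate_pass_fraction = qc$plate_pass_fraction_observed,
  plates_pass = qc$plates_pass, accept = qc$accept),
  file.path(out, "qc_acceptance.csv"), row.names = FALSE)

cat(sprintf("Plates: %d; median vehicle %%CV %.2f; %.1f%% of plates under 20%%\n",
            nrow(cvs), stats::median(cvs$cv_percent),
            100 * qc$plate_pass_fraction_observed))
cat(sprintf("Positive control: r = %.4f vs 1%% FN cutoff %.4f -> %s\n",
            qc$pearson_r, qc$cutoff_r,
            if (qc$pearson_pass) "pass" else "fail"))
cat(sprintf("Assay accepted: %s\n", qc$accept))
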