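#!/usr/bin/env Rscript
# Stage 2: normalization, historical envelope and hit calling.
#
# Converts raw wells to vehicle-normalized Log10Ratio profiles, inverts the
# loss-of-signal endpoints, builds the 95% historical-control envelope,
# derives per-endpoint bmad/cutoffs, and calls hits with LOECs for every
# blinded sample. Reports the duplicate hit-call concordance.

suppressPackageStartupMessages(library(phenotox))

data_dir <- "results/data"
out <- "results"
vocab <- read_endpoint_vocabulary(file.path(data_dir, "endpoints.csv"))
wells <- read_well_table(file.path(data_dir, "wells.csv"), vocab)
hist <- utils::read.table(file.path(data_dir, "historical_controls.tsv"),
                          sep = "\t", header = TRUE, stringsAsFactors = FALSE)
cfg <- pipeline_config()

pm <- compute_log10_ratios(wells, vocab)
pm_inv <- invert_down_endpoints(pm, vocab)
envelope <- build_envelope(hist, coverage = cfg$envelope_coverage)
hits <- hitcall_table(pm_inv, cfg)
conc <- concordance_summary(hits)

write_profile_matrix(pm, file.path(out, "profiles.tsv"))
write_profile_matrix(pm_inv, file.path(out, "profiles_inverted.tsv"))
write_envelope(envelope, file.path(out, "envelope.tsv"))
write_level5_table(hits, file.path(out, "hitcalls.csv"))
utils::write.csv(conc$per_chemical, file.path(out, "concordance.csv"),
                 row.names = FALSE)

cat(sprintf("Profiles: %d rows x %d endpoints\n", nrow(pm), ncol(pm)))
cat(sprintf("Median envelope half-width: %.4f Log10Ratio\n",
            stats::median((envelope$upper - envelope$lower) / 2)))
cat(sprintf("Active sample-endpoint pairs: %d of %d (%.1f%%)\n",
            sum(hits$hitc), nrow(hits), 100 * mean(hits$hitc)))
cat(sprintf("Replicate hit-call concordance: %.1f +/- %.1f%% over %d chemicals\n",
            conc$mean, conc$sd, nrow(conc$per_chemical)))
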