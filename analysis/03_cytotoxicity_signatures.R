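#!/usr/bin/env Rscript
# Stage 3: cytotoxicity flags and the nine-signature toxicity engine.
#
# Counts positive cytotoxicity endpoints per sample-concentration, flags
# overt and nonspecific cytotoxicity, evaluates the stepwise signature
# rules at each concentration, and summarizes to the chemical-level
# nd / NA / conc / >=conc table.

suppressPackageStartupMessages(library(phenotox))

data_dir <- "results/data"
out <- "results"
vocab <- read_endpoint_vocabulary(file.path(data_dir, "endpoints.csv"))
pm <- read_profile_matrix(file.path(out, "profiles.tsv"))
envelope <- read_envelope(file.path(out, "envelope.tsv"))
hits <- read_level5_table(file.path(out, "hitcalls.csv"))
cfg <- pipeline_config()

counts <- cytotox_counts(pm, hits, vocab)
ct_summary <- cytotox_summary(pm, hits, vocab, cfg)
calls <- evaluate_signatures(pm, envelope, vocab, cfg)
summaries <- summarize_signatures(calls, attr(pm, "replicate_of"))
tab <- signature_table(summaries)

utils::write.csv(counts, file.path(out, "cytotox_counts.csv"), row.names = FALSE)
utils::write.csv(ct_summary, file.path(out, "cytotox_summary.csv"),
                 row.names = FALSE)
utils::write.csv(calls, file.path(out, "signature_calls.csv"), row.names = FALSE)
write_signature_table(tab, file.path(out, "signature_table.csv"))

nonspec <- unique(ct_summary$chemical_id[ct_summary$nonspecific])
cat(sprintf("Nonspecifically cytotoxic chemicals (>=%d active cytotox endpoints): %d\n",
            cfg$nonspecific_cytotox_min, length(nonspec)))
listed <- summaries[summaries$status %in% c("listed_ge", "listed_at_top"), ]
cat("Chemicals listed per signature:\n")
print(table(listed$signature))
cat(sprintf("Signature table written for %d chemicals\n", nrow(tab)))
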