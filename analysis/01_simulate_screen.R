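#!/usr/bin/env Rscript
# Stage 1: simulate the screening campaign.
#
# Generates a synthetic screen of 50 chemicals over the 148-endpoint,
# 12-system panel (two blinded duplicate samples each, four-point dilution
# series 2.2/6.7/20/60 uM, 8 vehicle wells per plate), a 23-run historical
# vehicle-control collection, and a labeled reference profile database.
# Writes the raw inputs and the planted truth under results/data/.

suppressPackageStartupMessages(library(phenotox))

seed <- 20260928L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

vocab <- default_endpoints()
cfg <- pipeline_config(seed = seed)

scr <- generate_screen(vocab, cfg, n_chemicals = 50, seed = seed)
hist <- generate_historical_controls(vocab, noise_sd = cfg$noise_sd,
                                     seed = seed + 1L)
db <- generate_reference_db(vocab, n_per_archetype = 2,
                            noise_sd = cfg$noise_sd, seed = seed + 2L)

write_well_table(scr$wells, file.path(out, "wells.csv"))
write_endpoint_vocabulary(vocab, file.path(out, "endpoints.csv"))
utils::write.table(hist, file.path(out, "historical_controls.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(
  data.frame(label = db$label, mechanism = db$mechanism,
             concentration = db$concentration, n_cytotox = db$n_cytotox,
             db$values, check.names = FALSE),
  file.path(out, "reference_db.tsv"), sep = "\t", row.names = FALSE,
  quote = FALSE)
utils::write.csv(scr$truth$chemicals, file.path(out, "truth_chemicals.csv"),
                 row.names = FALSE)
utils::write.csv(scr$truth$expected_hits, file.path(out, "truth_hits.csv"),
                 row.names = FALSE)
utils::write.csv(scr$truth$expected_signatures,
                 file.path(out, "truth_signatures.csv"), row.names = FALSE)

cat("Simulated screen:", length(unique(scr$wells$chemical_id[scr$wells$well_role == "treatment"])),
    "chemicals,", nrow(scr$wells), "wells,",
    nrow(vocab), "endpoints\n")
cat("Archetype mix:\n")
print(table(scr$truth$chemicals$archetype))
cat("Outputs in", out, "\n")
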