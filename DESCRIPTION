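Package: phenotox
Title: Phenotypic Profiling of Chemicals Across Human Primary-Cell Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for rule-based toxicity profiling of chemicals
    screened across stimulated human primary-cell co-culture systems read out
    by biomarker endpoints. Converts raw well measurements to vehicle-
    normalized log10 fold-change profiles, derives per-endpoint response
    cutoffs from baseline median absolute deviation, assigns binary hit calls
    with lowest-effective-concentration estimates, flags overt and nonspecific
    cytotoxicity, evaluates a stepwise nine-rule toxicity-signature engine
    (acute, liver, organ, immunosuppression, thrombosis, skin irritation,
    skin sensitization, skin rash, vascular), searches reference profile
    databases by Pearson correlation, clusters response profiles with a batch
    self-organizing map, and applies plate and positive-control quality
    acceptance. Includes a synthetic-screen generator with planted ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
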