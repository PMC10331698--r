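# phenotox

Rule-based toxicity profiling of chemicals screened across stimulated
human primary-cell co-culture systems.

High-content phenotypic screens of this design test each chemical as two
blinded duplicate samples at a four-point dilution series across a panel
of co-culture systems (endothelial, bronchial, dermal, B/T-cell,
macrophage, smooth-muscle, fibroblast...), reading out 148 biomarker
endpoints. `phenotox` turns the raw well measurements into interpretable
toxicity calls for toxicologists and screening analysts:

* **Normalization** — each well is divided by the mean of the eight
  same-plate vehicle-control wells and log10 transformed
  (`x = log10(raw / vehicle mean)`, the *Log10Ratio*); loss-of-signal
  endpoints are inverted before hit calling.
* **Hit calls and potency** — per endpoint, the baseline median absolute
  deviation (`bmad`) is estimated from every sample's two lowest tested
  concentrations, the response cutoff is
  `coff = max(3 * bmad, log10 1.2)`, a sample is active when any
  concentration's response exceeds `coff`, and the lowest such
  concentration is the LOEC.
* **Cytotoxicity filtering** — overt cytotoxicity (SRB total protein or
  PBMC viability below −0.3 Log10Ratio), counts of positive cytotoxicity
  endpoints, nonspecific-cytotoxicity flags (2 or more), and removal of
  heavily cytotoxic profiles (more than 2) before profiling analyses.
* **Nine toxicity signatures** — a stepwise rule engine (acute toxicity
  masks everything else; liver, organ, immunosuppression, thrombosis,
  skin irritation, skin sensitization, skin rash, vascular toxicity) over
  specific endpoints, each condition combining a 95% historical-control
  envelope with a 20% effect-size bound; chemical-level summaries use the
  `nd` / `NA` / `conc` / `>=conc` convention.
* **Similarity search** — Pearson correlation against a labeled reference
  profile database, top 10 matches above r = 0.6.
* **SOM clustering** — deterministic batch self-organizing maps in two
  passes (7×7 on everything, 6×6 after cytotoxicity filtering).
* **Assay QC** — plate vehicle %CV and the positive-control Pearson test
  against a 1% false-negative leave-one-out cutoff.

A synthetic-screen generator plants known effects (inactive, cytotoxic,
cyclosporine-like, glucocorticoid-like, antimetabolite-like, and
single-signature archetypes) so the whole chain is testable end to end;
see `vignettes/phenotox-methods.Rmd` for the model, conventions and
limitations.

## Worked example

```r
library(phenotox)

vocab <- default_endpoints()                 # 148 endpoints, 12 systems
cfg   <- pipeline_config(seed = 7)           # all thresholds in one place

scr  <- generate_screen(vocab, cfg, n_chemicals = 12, seed = 7)
hist <- generate_historical_controls(vocab, seed = 8)
res  <- run_pipeline(cfg, scr$wells, hist, vocabulary = vocab)

res$concordance$mean                         # duplicate hit-call concordance
res$signature_table                          # chemical x signature summary
```

prints (abridged):

```
concordance: 96.1 +/- 1.8

 chemical_id             archetype acute_toxicity immunosuppression vascular_toxicity
     CHEM001              inactive             nd                nd                nd
     CHEM005 nonspecific_cytotoxic             60                nd                nd
     CHEM006     cyclosporine_like             nd              >=20                nd
     CHEM007   glucocorticoid_like             nd              >=20              >=20
```

Reading the table: the cytotoxic chemical trips the acute-toxicity
signature at its top tested concentration (60 µM), below which it is
clean; the cyclosporine-like suppressor is flagged for immunosuppression
at 20 µM and above in both duplicate samples; the glucocorticoid-like
chemical adds the SAA-driven vascular-toxicity alert. Duplicate samples
agree on 96% of their 148 binary hit calls.

The numbered scripts under `analysis/` run the same chain as a workflow —
`01_simulate_screen.R` through `05_qc.R` — writing each stage's tables
under `results/`.

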