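# Independent transcription of the nine signature rules, used as the
# oracle for the rule engine. Operates on one named value vector with a
# symmetric envelope; returns the 9 flags and evaluability after the
# acute-toxicity mask. Deliberately written as literal condition-by-
# condition prose-to-code transcription, independent of the package
# internals.
oracle_signatures <- function(v, vocab, env_half = 0.05) {
  outside <- function(e) v[e] < -env_half | v[e] > env_half
  srb <- vocab$endpoint_id[grepl(":SRB$", vocab$endpoint_id)]
  endo <- vocab$system[match(srb, vocab$endpoint_id)] %in%
    c("3C", "4H", "LPS", "Mphg")
  acute <- sum(v[srb] <= -0.3) >= 3 && any(v[srb[endo]] <= -0.3)

  liver <- v["3C:SRB"] <= -0.3
  organ <- outside("3C:Proliferation") && v["3C:Proliferation"] < -0.1 &&
    v["3C:SRB"] > -0.3
  immuno <- (outside("SAg:Proliferation") && v["SAg:Proliferation"] < -0.1) ||
    (outside("BT:sIgG") && v["BT:sIgG"] < -0.1 &&
       outside("BT:Proliferation") && v["BT:Proliferation"] < -0.1) ||
    (v["SAg:PBMC Cytotoxicity"] < -0.3) || (v["BT:PBMC Cytotoxicity"] < -0.3)
  thromb <- outside("3C:TF") && v["3C:TF"] > 0.1 && v["3C:SRB"] > -0.3
  irrit <- outside("LPS:PGE2") && v["LPS:PGE2"] > 0.1 &&
    !(outside("LPS:sTNFa") && v["LPS:sTNFa"] < 0)
  sens <- outside("HDF3CGF:Collagen III") && v["HDF3CGF:Collagen III"] < -0.1
  rash <- outside("HDF3CGF:VCAM-1") && v["HDF3CGF:VCAM-1"] > 0.1
  vasc <- outside("CASM3C:SAA") && v["CASM3C:SAA"] > 0.1

  flags <- stats::setNames(
    unname(c(acute, liver, organ, immuno, thromb, irrit, sens, rash, vasc)),
    c("acute_toxicity", "liver_toxicity", "organ_toxicity",
      "immunosuppression", "thrombosis", "skin_irritation",
      "skin_sensitization", "skin_rash", "vascular_toxicity"))
  if (acute) flags[-1L] <- FALSE
  evaluable <- c(acute_toxicity = TRUE,
                 stats::setNames(rep(!acute, 8L), names(flags)[-1L]))
  list(flags = unname(flags) & TRUE, evaluable = unname(evaluable),
       names = names(flags))
}

# build the class grid {below -0.3, in (-0.3,-0.1), in envelope, above 0.1}
# over a set of governing endpoints; all other endpoints 0
signature_grid <- function(endpoints, vocab = FULL_VOCAB,
                           classes = c(-0.4, -0.2, 0, 0.2)) {
  grid <- do.call(expand.grid, rep(list(classes), length(endpoints)))
  values <- matrix(0, nrow = nrow(grid), ncol = nrow(vocab),
                   dimnames = list(NULL, vocab$endpoint_id))
  for (j in seq_along(endpoints)) values[, endpoints[j]] <- grid[[j]]
  values
}

# engine-vs-oracle agreement over a grid of profile rows
check_grid_agreement <- function(values, vocab = FULL_VOCAB, env_half = 0.05) {
  pm <- pm_from_rows(values, vocab)
  calls <- evaluate_signatures(pm, flat_envelope(vocab, env_half), vocab)
  agree <- TRUE
  for (i in seq_len(nrow(values))) {
    want <- oracle_signatures(values[i, ], vocab, env_half)
    got <- calls[calls$sample_id == pm_samples(pm)[i], ]
    got <- got[match(want$names, got$signature), ]
    agree <- agree && identical(got$flagged, want$flags) &&
      identical(got$evaluable, want$evaluable)
  }
  agree
}
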