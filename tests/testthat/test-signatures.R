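test_that("rule engine matches the transcription oracle on exhaustive class grids", {
  vocab <- FULL_VOCAB
  grids <- list(
    acute = c("3C:SRB", "4H:SRB", "BE3C:SRB", "CASM3C:SRB", "MyoF:SRB"),
    liver = "3C:SRB",
    organ = c("3C:Proliferation", "3C:SRB"),
    immuno = c("SAg:Proliferation", "BT:sIgG", "BT:Proliferation",
               "SAg:PBMC Cytotoxicity", "BT:PBMC Cytotoxicity"),
    thrombosis = c("3C:TF", "3C:SRB"),
    irritation = c("LPS:PGE2", "LPS:sTNFa"),
    sensitization = "HDF3CGF:Collagen III",
    rash = "HDF3CGF:VCAM-1",
    vascular = "CASM3C:SAA")
  for (g in grids) {
    expect_true(check_grid_agreement(signature_grid(g, vocab), vocab))
  }
})

test_that("engine and oracle agree at the printed threshold boundaries", {
  vocab <- FULL_VOCAB
  boundary <- c(-0.4, -0.3, -0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2)
  for (eps in list(c("3C:SRB", "3C:Proliferation"),
                   c("LPS:PGE2", "LPS:sTNFa"),
                   c("3C:TF", "3C:SRB"))) {
    expect_true(check_grid_agreement(
      signature_grid(eps, vocab, classes = boundary), vocab))
  }
})

test_that("acute toxicity needs 3 low SRB endpoints incl. an endothelial system", {
  vocab <- FULL_VOCAB
  env <- flat_envelope(vocab)
  # three low SRBs, one endothelial (3C) -> acute; everything else NA
  pm <- pm_from_rows(rbind(profile_row(
    vocab, c("3C:SRB" = -0.4, "4H:SRB" = -0.4, "BE3C:SRB" = -0.4))), vocab)
  calls <- evaluate_signatures(pm, env, vocab)
  expect_true(calls$flagged[calls$signature == "acute_toxicity"])
  others <- calls[calls$signature != "acute_toxicity", ]
  expect_false(any(others$evaluable))
  expect_false(any(others$flagged))

  # three low SRBs but none endothelial -> no acute
  pm <- pm_from_rows(rbind(profile_row(
    vocab, c("BE3C:SRB" = -0.4, "CASM3C:SRB" = -0.4, "MyoF:SRB" = -0.4))), vocab)
  calls <- evaluate_signatures(pm, env, vocab)
  expect_false(calls$flagged[calls$signature == "acute_toxicity"])
})

test_that("liver toxicity flags and evaluation continues; organ guard blocks", {
  vocab <- FULL_VOCAB
  env <- flat_envelope(vocab)
  pm <- pm_from_rows(rbind(profile_row(vocab, c("3C:SRB" = -0.35))), vocab)
  calls <- evaluate_signatures(pm, env, vocab)
  get <- function(sig) calls[calls$signature == sig, ]
  expect_false(get("acute_toxicity")$flagged)  # only one SRB endpoint low
  expect_true(get("liver_toxicity")$flagged)
  expect_true(all(calls$evaluable))            # liver does not mask
  expect_false(get("organ_toxicity")$flagged)  # 3C:SRB <= -0.3 fails "> -0.3"
})

test_that("an isolated SAA increase raises only vascular toxicity", {
  vocab <- FULL_VOCAB
  pm <- pm_from_rows(rbind(profile_row(vocab, c("CASM3C:SAA" = 0.2))), vocab)
  calls <- evaluate_signatures(pm, flat_envelope(vocab), vocab)
  expect_equal(calls$signature[calls$flagged], "vascular_toxicity")
})

test_that("flagged calls are always evaluable and acute is always evaluable", {
  vocab <- FULL_VOCAB
  set.seed(51)
  values <- matrix(rnorm(40 * nrow(vocab), sd = 0.25), nrow = 40,
                   dimnames = list(NULL, vocab$endpoint_id))
  calls <- evaluate_signatures(pm_from_rows(values, vocab),
                               flat_envelope(vocab), vocab)
  expect_true(all(calls$evaluable[calls$flagged]))
  expect_true(all(calls$evaluable[calls$signature == "acute_toxicity"]))
})

test_that("a missing required endpoint is reported with the signature name", {
  vocab <- FULL_VOCAB
  values <- matrix(0, nrow = 1,
                   ncol = nrow(vocab) - 1,
                   dimnames = list(NULL, setdiff(vocab$endpoint_id, "CASM3C:SAA")))
  pm <- pm_from_rows(values, vocab[vocab$endpoint_id != "CASM3C:SAA", ])
  expect_error(evaluate_signatures(pm, flat_envelope(vocab), vocab),
               "vascular_toxicity.*CASM3C:SAA")
})

test_that("summarization follows the nd/NA/top/>= convention", {
  concs <- c(2.2, 6.7, 20, 60)
  mk_calls <- function(flag_concs, eval_concs = concs, samples = c("S1", "S2")) {
    do.call(rbind, lapply(samples, function(s) {
      do.call(rbind, lapply(SIGNATURE_NAMES, function(sig) data.frame(
        sample_id = s, concentration = concs, signature = sig,
        flagged = sig == "vascular_toxicity" & concs %in% flag_concs,
        evaluable = if (sig == "acute_toxicity") TRUE else concs %in% eval_concs,
        stringsAsFactors = FALSE)))
    }))
  }
  rep_of <- c(S1 = "C1", S2 = "C1")
  get_vt <- function(summ) summ[summ$signature == "vascular_toxicity", ]

  s <- get_vt(summarize_signatures(mk_calls(c(20, 60)), rep_of))
  expect_equal(s$status, "listed_ge"); expect_equal(s$min_conc, 20)

  s <- get_vt(summarize_signatures(mk_calls(60), rep_of))
  expect_equal(s$status, "listed_at_top"); expect_equal(s$min_conc, 60)

  s <- get_vt(summarize_signatures(mk_calls(6.7), rep_of))
  expect_equal(s$status, "nd")  # one non-top concentration only

  s <- get_vt(summarize_signatures(mk_calls(numeric(0)), rep_of))
  expect_equal(s$status, "nd")

  # masked everywhere -> NA
  s <- get_vt(summarize_signatures(mk_calls(numeric(0), eval_concs = numeric(0)),
                                   rep_of))
  expect_equal(s$status, "NA")
})

test_that("a chemical-level flag requires both duplicate samples flagged", {
  concs <- c(2.2, 6.7, 20, 60)
  calls <- do.call(rbind, lapply(c("S1", "S2"), function(s) {
    do.call(rbind, lapply(SIGNATURE_NAMES, function(sig) data.frame(
      sample_id = s, concentration = concs, signature = sig,
      flagged = sig == "thrombosis" & s == "S1" & concs >= 20,  # S2 never
      evaluable = TRUE, stringsAsFactors = FALSE)))
  }))
  summ <- summarize_signatures(calls, c(S1 = "C1", S2 = "C1"))
  expect_equal(summ$status[summ$signature == "thrombosis"], "nd")
})

test_that("extending the acute mask never adds listed concentrations", {
  concs <- c(2.2, 6.7, 20, 60)
  base_calls <- function(masked_concs) {
    do.call(rbind, lapply(c("S1", "S2"), function(s) {
      do.call(rbind, lapply(SIGNATURE_NAMES, function(sig) data.frame(
        sample_id = s, concentration = concs, signature = sig,
        flagged = (sig == "acute_toxicity" & concs %in% masked_concs) |
          (sig == "skin_rash" & !concs %in% masked_concs & concs >= 20),
        evaluable = sig == "acute_toxicity" | !concs %in% masked_concs,
        stringsAsFactors = FALSE)))
    }))
  }
  rep_of <- c(S1 = "C1", S2 = "C1")
  listed <- function(masked) {
    s <- summarize_signatures(base_calls(masked), rep_of)
    s <- s[s$signature == "skin_rash", ]
    if (s$status %in% c("nd", "NA")) 0 else
      sum(concs[concs >= s$min_conc] %in% setdiff(concs, masked))
  }
  expect_true(listed(c(20, 60)) <= listed(60))
  expect_true(listed(60) <= listed(numeric(0)))
})

test_that("signature table renders cells and round-trips", {
  summ <- data.frame(
    chemical_id = "C1",
    signature = SIGNATURE_NAMES,
    status = c("nd", "NA", "listed_at_top", "listed_ge", rep("nd", 5)),
    min_conc = c(NA, NA, 60, 1.5, rep(NA, 5)),
    stringsAsFactors = FALSE)
  tab <- signature_table(summ)
  expect_equal(tab$acute_toxicity, "nd")
  expect_equal(tab$liver_toxicity, "NA")
  expect_equal(tab$organ_toxicity, "60")
  expect_equal(tab$immunosuppression, ">=1.5")
  back <- parse_signature_table(tab)
  back <- back[match(paste(summ$chemical_id, summ$signature),
                     paste(back$chemical_id, back$signature)), ]
  expect_equal(back$status, summ$status)
  expect_equal(back$min_conc, summ$min_conc)

  empty <- signature_table(summ[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(SIGNATURE_NAMES %in% names(empty)))
})
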