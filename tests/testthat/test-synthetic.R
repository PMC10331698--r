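test_that("a noiseless inactive screen normalizes to an all-zero matrix", {
  vocab <- small_vocab()
  cfg <- pipeline_config(noise_sd = 0)
  scr <- generate_screen(vocab, cfg, n_chemicals = 3, noise_sd = 0, seed = 1,
                         archetype_mix = c(inactive = 1))
  pm <- compute_log10_ratios(scr$wells, vocab)
  expect_equal(max(abs(unclass(pm))), 0)
  expect_equal(nrow(pm), 3 * 2 * 4)  # chemicals x duplicates x concentrations
})

test_that("screen generation is reproducible under a fixed seed", {
  vocab <- small_vocab()
  cfg <- pipeline_config()
  mix <- c(inactive = 0.5, `single_signature:thrombosis` = 0.5)
  a <- generate_screen(vocab, cfg, n_chemicals = 4, seed = 5, archetype_mix = mix)
  b <- generate_screen(vocab, cfg, n_chemicals = 4, seed = 5, archetype_mix = mix)
  c <- generate_screen(vocab, cfg, n_chemicals = 4, seed = 6, archetype_mix = mix)
  expect_identical(a$wells, b$wells)
  expect_identical(a$truth$expected_hits, b$truth$expected_hits)
  expect_false(identical(a$wells$raw_value, c$wells$raw_value))
})

test_that("every plate carries exactly 8 vehicle wells per endpoint", {
  vocab <- small_vocab()
  scr <- generate_screen(vocab, pipeline_config(), n_chemicals = 15, seed = 2,
                         archetype_mix = c(inactive = 1))
  expect_silent(validate_well_table(scr$wells, vocab))
  veh <- scr$wells[scr$wells$well_role == "vehicle_control", ]
  counts <- table(paste(veh$plate_id, veh$endpoint_id))
  expect_true(all(counts == 8))
  # 15 chemicals at batch size 12 -> 2 plates per endpoint
  expect_equal(length(unique(veh$plate_id)), 2L * nrow(vocab))
})

test_that("the cytotoxic archetype yields exactly k active cytotox endpoints at 60 uM", {
  vocab <- FULL_VOCAB
  cfg <- pipeline_config(noise_sd = 0)
  scr <- generate_screen(vocab, cfg, n_chemicals = 2, noise_sd = 0, seed = 3,
                         archetype_mix = c(nonspecific_cytotoxic = 1),
                         n_cytotox = 3)
  pm <- compute_log10_ratios(scr$wells, vocab)
  hits <- hitcall_table(invert_down_endpoints(pm, vocab), cfg)
  s1 <- unique(hits$sample_id)[1]
  expect_equal(count_active_cytotox(hits, vocab, 60, sample_id = s1), 3L)
  expect_equal(count_active_cytotox(hits, vocab, 6.7, sample_id = s1), 0L)
})

test_that("an archetype that needs an absent endpoint is a configuration error", {
  vocab <- small_vocab()  # lacks the BT cytokine endpoints
  expect_error(generate_screen(vocab, pipeline_config(), n_chemicals = 2,
                               archetype_mix = c(cyclosporine_like = 1)),
               "configuration error")
})

test_that("historical controls collapse at zero noise and match Normal quantiles", {
  vocab <- small_vocab()
  hist0 <- generate_historical_controls(vocab, noise_sd = 0, seed = 1)
  env <- build_envelope(hist0)
  expect_true(all(env$lower == 0 & env$upper == 0))

  one_ep <- vocab[1, ]
  hist <- generate_historical_controls(one_ep, n_runs = 1250,
                                       wells_per_run = 8, noise_sd = 0.05,
                                       seed = 4)
  expect_equal(nrow(hist), 10000L)
  env <- build_envelope(hist)
  expect_lt(abs(env$lower + 0.098), 0.005)
  expect_lt(abs(env$upper - 0.098), 0.005)

  h1 <- generate_historical_controls(vocab, noise_sd = 0.05, seed = 9)
  h2 <- generate_historical_controls(vocab, noise_sd = 0.05, seed = 9)
  expect_identical(h1, h2)
})

test_that("reference profiles sit on archetype means at zero noise", {
  vocab <- FULL_VOCAB
  db <- generate_reference_db(vocab, n_per_archetype = 1, noise_sd = 0, seed = 5)
  specs <- archetype_specs(vocab)
  mu <- profile_row(vocab, specs$cyclosporine_like$effects)
  expect_equal(unname(db$values["cyclosporine_like.1", ]), unname(mu))
  # cytotoxic archetype rows carry their planted cytotoxicity count
  expect_equal(db$n_cytotox[db$mechanism == "nonspecific_cytotoxic"], 3L)
  expect_equal(db$n_cytotox[db$mechanism == "cyclosporine_like"], 0L)
})

test_that("same-archetype profiles correlate strongly; orthogonal ones weakly", {
  vocab <- FULL_VOCAB
  db <- generate_reference_db(vocab, n_per_archetype = 2, noise_sd = 0.05,
                              seed = 6)
  v <- db$values
  mates <- pearson_profile(v["cyclosporine_like.1", ], v["cyclosporine_like.2", ])
  expect_gt(mates, 0.7)
  cross <- pearson_profile(v["cyclosporine_like.1", ],
                           v["single_signature:skin_rash.1", ])
  expect_lt(abs(cross), 0.3)
})

test_that("planted truth is internally consistent with the ramp and floor", {
  vocab <- FULL_VOCAB
  scr <- generate_screen(vocab, pipeline_config(noise_sd = 0), n_chemicals = 13,
                         noise_sd = 0, seed = 7)
  tr <- scr$truth
  # every expected hit has a LOEC among the tested concentrations
  hits1 <- tr$expected_hits[tr$expected_hits$hitc == 1L, ]
  expect_true(all(hits1$loec_uM %in% tr$concentrations))
  # inactive chemicals plant nothing and expect nothing
  inact <- tr$chemicals$chemical_id[tr$chemicals$archetype == "inactive"]
  expect_true(all(tr$expected_hits$hitc[tr$expected_hits$chemical_id %in% inact] == 0L))
  expect_true(all(tr$expected_signatures$status[
    tr$expected_signatures$chemical_id %in% inact] == "nd"))
})
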