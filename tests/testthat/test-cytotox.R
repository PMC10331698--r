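test_that("overt flagging applies the -0.3 rule with a strict boundary", {
  vocab <- small_vocab()
  rows <- rbind(
    profile_row(vocab, c("3C:SRB" = -0.35)),
    profile_row(vocab),
    profile_row(vocab, c("3C:SRB" = -0.30)),       # boundary: not overt
    profile_row(vocab, c("CASM3C:SAA" = -0.9)))    # not a cytotox endpoint
  pm <- pm_from_rows(rows, vocab)
  ov <- flag_overt(pm, vocab)
  expect_equal(ov$overt, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ov$cytotox_endpoints_below[1], "3C:SRB")
  # inclusive variant flags the boundary value
  expect_true(flag_overt(pm, vocab, strict = FALSE)$overt[3])
})

test_that("active cytotoxicity endpoints are counted by LOEC <= concentration", {
  vocab <- small_vocab()
  hits <- data.frame(
    sample_id = "S1", chemical_id = "C1",
    endpoint_id = c("3C:SRB", "4H:SRB", "CASM3C:SAA", "LPS:SRB"),
    bmad = 0, coff = 0.08,
    hitc = c(1L, 1L, 1L, 0L),
    loec_uM = c(20, 60, 2.2, NA), stringsAsFactors = FALSE)
  expect_equal(count_active_cytotox(hits, vocab, 60), 2L)
  expect_equal(count_active_cytotox(hits, vocab, 20), 1L)
  expect_equal(count_active_cytotox(hits, vocab, 6.7), 0L)
  expect_equal(count_active_cytotox(hits[hits$hitc == 0L, ], vocab, 60), 0L)
})

test_that("nonspecific cytotoxicity needs two or more active endpoints", {
  vocab <- small_vocab()
  one <- data.frame(sample_id = "S1", chemical_id = "C1",
                    endpoint_id = "3C:SRB", bmad = 0, coff = 0.08,
                    hitc = 1L, loec_uM = 60, stringsAsFactors = FALSE)
  expect_false(flag_nonspecific(one, vocab, c(2.2, 6.7, 20, 60))$nonspecific)

  three <- data.frame(sample_id = "S1", chemical_id = "C1",
                      endpoint_id = c("3C:SRB", "4H:SRB", "LPS:SRB"),
                      bmad = 0, coff = 0.08, hitc = 1L, loec_uM = 60,
                      stringsAsFactors = FALSE)
  res <- flag_nonspecific(three, vocab, c(2.2, 6.7, 20, 60))
  expect_true(res$nonspecific)
  expect_equal(res$active_concentrations, 60)
})

test_that("adding an active cytotox endpoint never clears the nonspecific flag", {
  vocab <- small_vocab()
  cyto <- cytotox_endpoints(vocab)
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(length(cyto), 1)
    eps <- sample(cyto, n)
    hits <- data.frame(sample_id = "S1", chemical_id = "C1",
                       endpoint_id = eps, bmad = 0, coff = 0.08, hitc = 1L,
                       loec_uM = sample(c(20, 60), n, replace = TRUE),
                       stringsAsFactors = FALSE)
    before <- flag_nonspecific(hits, vocab, c(20, 60))$nonspecific
    extra <- setdiff(cyto, eps)
    if (length(extra) == 0) next
    more <- rbind(hits, data.frame(sample_id = "S1", chemical_id = "C1",
                                   endpoint_id = extra[1], bmad = 0,
                                   coff = 0.08, hitc = 1L, loec_uM = 60,
                                   stringsAsFactors = FALSE))
    after <- flag_nonspecific(more, vocab, c(20, 60))$nonspecific
    expect_true(after >= before)
  }
})

test_that("chemical summary averages counts over duplicates (fractional counts)", {
  vocab <- small_vocab()
  # duplicate samples with 5 and 4 active cytotox endpoints at 20 uM -> 4.5
  cyto <- cytotox_endpoints(vocab)
  mk <- function(s, eps) data.frame(sample_id = s, chemical_id = "C1",
                                    endpoint_id = eps, bmad = 0, coff = 0.08,
                                    hitc = 1L, loec_uM = 20,
                                    stringsAsFactors = FALSE)
  hits <- rbind(mk("S1", cyto[1:5]), mk("S2", cyto[1:4]))
  rows <- rbind(profile_row(vocab), profile_row(vocab))
  pm <- profile_matrix(rows, c("S1", "S2"), c(20, 20),
                       c(S1 = "C1", S2 = "C1"))
  summ <- cytotox_summary(pm, hits, vocab)
  expect_equal(summ$mean_n_cytotox, 4.5)
  expect_true(summ$nonspecific)
})

test_that("profiling filter equals a brute-force row filter", {
  vocab <- small_vocab()
  set.seed(42)
  values <- matrix(rnorm(20 * nrow(vocab), sd = 0.1), nrow = 20,
                   dimnames = list(NULL, vocab$endpoint_id))
  samples <- sprintf("S%02d", 1:20)
  pm <- profile_matrix(values, samples, rep(60, 20),
                       stats::setNames(samples, samples))
  counts <- data.frame(sample_id = samples, concentration = 60,
                       n_cytotox = sample(0:5, 20, replace = TRUE))
  filt <- filter_for_profiling(pm, counts, max_allowed = 2)
  keep <- counts$n_cytotox <= 2
  got <- unclass(filt)
  attributes(got) <- attributes(got)[c("dim", "dimnames")]
  expect_equal(got, unclass(pm)[keep, , drop = FALSE])
  expect_equal(pm_samples(filt), samples[keep])
  # boundary: a count of exactly 2 is retained, 3 is removed
  expect_true(all(counts$n_cytotox[match(pm_samples(filt), samples)] <= 2))
})
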