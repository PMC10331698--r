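test_that("bmad matches the hand-computed scaled MAD", {
  vocab <- small_vocab()
  # pool {-0.01, 0.00, 0.01, 0.02}: median 0.005, raw MAD 0.010 -> 0.014826
  values <- matrix(0, nrow = 4, ncol = nrow(vocab),
                   dimnames = list(NULL, vocab$endpoint_id))
  values[, "3C:SRB"] <- c(-0.01, 0.00, 0.01, 0.02)
  pm <- profile_matrix(values, rep(c("S1", "S2"), each = 2),
                       rep(c(2.2, 6.7), 2), c(S1 = "C1", S2 = "C2"))
  expect_equal(compute_bmad(pm, "3C:SRB"), 0.014826, tolerance = 1e-9)
  expect_equal(compute_bmad(pm, "3C:SRB", constant = 1), 0.010)

  # all-zero pool and single-value pool degenerate to 0
  expect_equal(compute_bmad(pm, "3C:TF"), 0)
  one <- profile_matrix(values[1, , drop = FALSE], "S1", 2.2, c(S1 = "C1"))
  expect_equal(compute_bmad(one, "3C:SRB"), 0)
})

test_that("bmad pools only each sample's two lowest concentrations", {
  vocab <- small_vocab()
  values <- matrix(0, nrow = 4, ncol = nrow(vocab),
                   dimnames = list(NULL, vocab$endpoint_id))
  values[, "3C:SRB"] <- c(0.01, 0.02, 5, 5)  # big responses at high concs
  pm <- profile_matrix(values, rep("S1", 4), c(2.2, 6.7, 20, 60),
                       c(S1 = "C1"))
  expect_equal(compute_bmad(pm, "3C:SRB"),
               stats::mad(c(0.01, 0.02), constant = 1.4826))
})

test_that("cutoff takes the max of 3*bmad and the log10(1.2) floor", {
  expect_equal(compute_cutoff(0), log10(1.2))
  expect_equal(compute_cutoff(0), 0.0791812, tolerance = 1e-6)
  expect_equal(compute_cutoff(0.05), 0.15)
  expect_equal(compute_cutoff(0.02), log10(1.2))  # 0.06 < floor
  expect_error(compute_cutoff(0.1, floor_fold = 1), "exceed 1")
  expect_error(compute_cutoff(-0.1), "bmad")
})

test_that("hit call scans for the first exceedance, strict at the cutoff", {
  concs <- c(2.2, 6.7, 20, 60)
  h <- call_hits(c(0.01, 0.02, 0.10, 0.20), concs, 0.0792)
  expect_equal(h$hitc, 1L)
  expect_equal(h$loec, 20)

  h <- call_hits(c(0.01, 0.02, 0.03, 0.05), concs, 0.0792)
  expect_equal(h$hitc, 0L)
  expect_true(is.na(h$loec))

  h <- call_hits(c(0.5, 0.01, 0.01, 0.01), concs, 0.0792)
  expect_equal(h$loec, 2.2)

  # a response exactly at the cutoff is inactive
  h <- call_hits(c(0, 0, 0.0792, 0), concs, 0.0792)
  expect_equal(h$hitc, 0L)
})

test_that("hitcall_table agrees with a brute-force per-series oracle", {
  vocab <- small_vocab()
  cfg <- pipeline_config()
  set.seed(31)
  scr <- generate_screen(vocab, cfg, n_chemicals = 6, noise_sd = 0.08,
                         seed = 31,
                         archetype_mix = c(inactive = 0.5,
                                           `single_signature:thrombosis` = 0.25,
                                           `single_signature:immunosuppression` = 0.25))
  pm <- invert_down_endpoints(compute_log10_ratios(scr$wells, vocab), vocab)
  hits <- hitcall_table(pm, cfg)
  bmad <- compute_bmad_all(pm, cfg$mad_constant)
  for (i in sample(nrow(hits), 25)) {
    row <- hits[i, ]
    idx <- pm_samples(pm) == row$sample_id
    resp <- unclass(pm)[idx, row$endpoint_id]
    co <- pm_concs(pm)[idx]
    coff <- max(3 * bmad[row$endpoint_id], log10(1.2))
    exceeds <- resp > coff
    expect_equal(row$hitc, as.integer(any(exceeds)))
    if (any(exceeds)) expect_equal(row$loec_uM, min(co[exceeds]))
    expect_equal(row$coff, coff)
  }
})

test_that("raising the cutoff never creates hits nor lowers a LOEC", {
  set.seed(32)
  concs <- c(2.2, 6.7, 20, 60)
  for (rep in 1:200) {
    resp <- rnorm(4, 0, 0.15)
    c1 <- runif(1, 0.02, 0.3)
    c2 <- c1 + runif(1, 0, 0.2)
    low <- call_hits(resp, concs, c1)
    high <- call_hits(resp, concs, c2)
    expect_true(high$hitc <= low$hitc)
    if (high$hitc == 1L) expect_true(high$loec >= low$loec)
  }
})

test_that("replicate concordance counts agreeing endpoints", {
  eps <- sprintf("E%03d", 1:148)
  a <- stats::setNames(rep(0L, 148), eps)
  expect_equal(replicate_concordance(a, a), 100)
  b <- a; b[1] <- 1L
  expect_equal(replicate_concordance(a, b), 100 * 147 / 148)
  expect_equal(replicate_concordance(a, 1L - a), 0)
  expect_error(replicate_concordance(a, a[-1]), "different endpoint sets")
})

test_that("chemical-level activity is active-in-either with the minimum LOEC", {
  hits <- data.frame(
    sample_id = c("S1", "S2", "S1", "S2"),
    chemical_id = "C1",
    endpoint_id = c("A", "A", "B", "B"),
    bmad = 0, coff = 0.08,
    hitc = c(1L, 0L, 1L, 1L),
    loec_uM = c(20, NA, 60, 6.7),
    stringsAsFactors = FALSE)
  ch <- chemical_hits(hits)
  expect_equal(ch$hitc[ch$endpoint_id == "A"], 1L)
  expect_equal(ch$loec_uM[ch$endpoint_id == "A"], 20)
  expect_equal(ch$loec_uM[ch$endpoint_id == "B"], 6.7)
})
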