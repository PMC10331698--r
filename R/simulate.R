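#' Chemical archetypes with planted effects
#'
#' Each archetype is a named vector of full planted effects (Log10Ratio
#' units, reached at the top concentration) over specific endpoints.
#' Effects ramp with concentration: zero at the two lowest tested
#' concentrations (so the baseline-variability estimate stays clean), half
#' the full effect at the third, full effect at the top.
#'
#' The archetypes emulate the behavior classes seen in phenotypic screens:
#' * `inactive` — no planted effect anywhere.
#' * `nonspecific_cytotoxic` — `n_cytotox` SRB total-protein endpoints
#'   suppressed by -0.5 (the first endpoints of the SRB panel, which
#'   include endothelial systems, so acute toxicity is triggered when
#'   `n_cytotox >= 3`).
#' * `cyclosporine_like` — strong suppression of secreted IgG, B/T-cell
#'   proliferation and T-cell cytokines (BT and SAg systems).
#' * `glucocorticoid_like` — cytokine and IgG suppression with an SAA
#'   acute-phase increase in coronary smooth muscle cells.
#' * `antimetabolite_like` — IgG suppression plus broad antiproliferative
#'   effects across cell types.
#' * `single_signature:<name>` — the minimal planted effect that raises
#'   exactly one toxicity signature (one per non-acute signature).
#'
#' @param vocabulary an [endpoint_vocabulary()].
#' @param n_cytotox SRB endpoints hit by the cytotoxic archetype.
#' @param archetypes archetype names to return (default all); only the
#'   requested archetypes are validated against the vocabulary, so reduced
#'   vocabularies can still drive the archetypes they support.
#' @return named list of archetypes, each `list(name, effects)`.
#' @export
archetype_specs <- function(vocabulary, n_cytotox = 3L, archetypes = NULL) {
  srb_order <- c("3C:SRB", "4H:SRB", "BE3C:SRB", "BF4T:SRB", "CASM3C:SRB",
                 "HDF3CGF:SRB", "KF3CT:SRB", "LPS:SRB", "Mphg:SRB",
                 "MyoF:SRB", "SAg:SRB")
  srb_order <- srb_order[srb_order %in% vocabulary$endpoint_id]
  if (n_cytotox > length(srb_order)) {
    stop("configuration error: cytotoxic archetype needs ", n_cytotox,
         " SRB endpoints but the vocabulary has ", length(srb_order))
  }
  specs <- list(
    inactive = numeric(0),
    nonspecific_cytotoxic = stats::setNames(
      rep(-0.5, n_cytotox), srb_order[seq_len(n_cytotox)]),
    cyclosporine_like = c("BT:sIgG" = -0.5, "BT:Proliferation" = -0.5,
                          "SAg:Proliferation" = -0.5, "BT:sIL-2" = -0.4,
                          "BT:sIL-6" = -0.4, "BT:sIL-17A" = -0.4,
                          "BT:sTNFa" = -0.4),
    glucocorticoid_like = c("BT:sIgG" = -0.4, "BT:Proliferation" = -0.4,
                            "Mphg:sIL-10" = -0.4, "CASM3C:SAA" = 0.5,
                            "BT:sIL-2" = -0.4, "BT:sTNFa" = -0.4),
    antimetabolite_like = c("BT:sIgG" = -0.5, "BT:Proliferation" = -0.5,
                            "SAg:Proliferation" = -0.4,
                            "3C:Proliferation" = -0.4,
                            "HDF3CGF:Proliferation" = -0.4,
                            "CASM3C:Proliferation" = -0.4),
    `single_signature:liver_toxicity` = c("3C:SRB" = -0.4),
    `single_signature:organ_toxicity` = c("3C:Proliferation" = -0.4),
    `single_signature:immunosuppression` = c("SAg:Proliferation" = -0.4),
    `single_signature:thrombosis` = c("3C:TF" = 0.4),
    `single_signature:skin_irritation` = c("LPS:PGE2" = 0.4),
    `single_signature:skin_sensitization` = c("HDF3CGF:Collagen III" = -0.4),
    `single_signature:skin_rash` = c("HDF3CGF:VCAM-1" = 0.4),
    `single_signature:vascular_toxicity` = c("CASM3C:SAA" = 0.4)
  )
  if (!is.null(archetypes)) {
    unknown <- setdiff(archetypes, names(specs))
    if (length(unknown) > 0L) {
      stop("unknown archetype(s): ", paste(unknown, collapse = ", "))
    }
    specs <- specs[archetypes]
  }
  for (nm in names(specs)) {
    miss <- setdiff(names(specs[[nm]]), vocabulary$endpoint_id)
    if (length(miss) > 0L) {
      stop("configuration error: archetype ", nm,
           " requires endpoint(s) absent from the vocabulary: ",
           paste(miss, collapse = ", "))
    }
  }
  lapply(stats::setNames(names(specs), names(specs)),
         function(nm) list(name = nm, effects = specs[[nm]]))
}

#' Default archetype mixture
#' @return named numeric proportions summing to 1.
#' @export
default_archetype_mix <- function() {
  singles <- paste0("single_signature:",
                    c("liver_toxicity", "organ_toxicity", "immunosuppression",
                      "thrombosis", "skin_irritation", "skin_sensitization",
                      "skin_rash", "vascular_toxicity"))
  c(stats::setNames(c(0.30, 0.10, 0.10, 0.10, 0.10),
                    c("inactive", "nonspecific_cytotoxic", "cyclosporine_like",
                      "glucocorticoid_like", "antimetabolite_like")),
    stats::setNames(rep(0.30 / length(singles), length(singles)), singles))
}

concentration_ramp <- function(n_conc) {
  if (n_conc < 2L) return(rep(1, n_conc))
  ramp <- numeric(n_conc)
  idx <- seq_len(n_conc) > 2L
  if (any(idx)) ramp[idx] <- seq_len(sum(idx)) / sum(idx)
  ramp
}

#' Generate a synthetic screen with known ground truth
#'
#' Emulates the screening design: every chemical is screened as two blinded
#' duplicate samples at a four-point dilution series, one well per
#' endpoint, with 8 vehicle-control wells per plate and one plate per
#' (endpoint, chemical batch). Measurement noise is multiplicative
#' lognormal on raw values, so after vehicle normalization the Log10Ratio
#' of a well is approximately Normal(planted effect, `noise_sd`).
#'
#' @param vocabulary an [endpoint_vocabulary()].
#' @param config a [pipeline_config()].
#' @param n_chemicals number of chemicals.
#' @param archetype_mix named proportions over archetype names (must sum
#'   to 1); chemicals are allocated deterministically.
#' @param noise_sd measurement noise in Log10Ratio units.
#' @param seed random seed.
#' @param uniform_effect if non-`NULL`, every planted effect magnitude is
#'   replaced by this value (signs preserved) — used for calibration
#'   studies at a fixed effect size.
#' @param n_cytotox SRB endpoints hit by the cytotoxic archetype.
#' @return list with `wells` (a well table) and `truth` (a `screen_truth`:
#'   chemical archetypes, planted effects, expected hit calls and LOECs,
#'   expected cytotoxicity counts, expected signature summaries).
#' @export
generate_screen <- function(vocabulary, config = pipeline_config(),
                            n_chemicals = 30L,
                            archetype_mix = default_archetype_mix(),
                            noise_sd = config$noise_sd,
                            seed = config$seed,
                            uniform_effect = NULL,
                            n_cytotox = 3L) {
  if (abs(sum(archetype_mix) - 1) > 1e-8) stop("archetype_mix must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  specs <- archetype_specs(vocabulary, n_cytotox = n_cytotox,
                           archetypes = names(archetype_mix))
  if (!is.null(uniform_effect)) {
    specs <- lapply(specs, function(a) {
      a$effects <- sign(a$effects) * uniform_effect
      a
    })
  }

  # deterministic allocation of chemicals to archetypes
  alloc <- diff(c(0L, round(cumsum(archetype_mix) * n_chemicals)))
  arch_of_chem <- rep(names(archetype_mix), alloc)
  chem_ids <- sprintf("CHEM%03d", seq_len(n_chemicals))
  sample_ids <- sprintf("S%04d", seq_len(2L * n_chemicals))
  replicate_of <- stats::setNames(rep(chem_ids, each = 2L), sample_ids)

  concs <- config$concentrations
  n_c <- length(concs)
  ramp <- concentration_ramp(n_c)
  eps <- vocabulary$endpoint_id
  n_e <- length(eps)

  # full-effect matrix: chemicals x endpoints
  E <- matrix(0, nrow = n_chemicals, ncol = n_e,
              dimnames = list(chem_ids, eps))
  for (i in seq_len(n_chemicals)) {
    eff <- specs[[arch_of_chem[i]]]$effects
    if (length(eff) > 0L) E[i, names(eff)] <- eff
  }

  batch <- ceiling(seq_len(n_chemicals) / config$batch_size)
  n_b <- max(batch)
  baseline <- 100

  # treatment wells: sample-major, then concentration, then endpoint
  samp_i <- rep(seq_len(2L * n_chemicals), each = n_c * n_e)
  chem_i <- (samp_i + 1L) %/% 2L
  conc_i <- rep(rep(seq_len(n_c), each = n_e), times = 2L * n_chemicals)
  ep_i <- rep(seq_len(n_e), times = n_c * 2L * n_chemicals)
  planted <- E[cbind(chem_i, ep_i)] * ramp[conc_i]

  set.seed(seed)
  n_trt <- length(planted)
  log_val <- planted + stats::rnorm(n_trt, 0, noise_sd)
  trt <- data.frame(
    plate_id = sprintf("P%03d_%02d", ep_i, batch[chem_i]),
    well_id = sprintf("W%07d", seq_len(n_trt)),
    sample_id = sample_ids[samp_i],
    chemical_id = chem_ids[chem_i],
    concentration_uM = concs[conc_i],
    endpoint_id = eps[ep_i],
    raw_value = baseline * 10^log_val,
    well_role = "treatment",
    stringsAsFactors = FALSE
  )

  # 8 vehicle wells per (endpoint, batch) plate
  veh_ep <- rep(seq_len(n_e), each = 8L * n_b)
  veh_b <- rep(rep(seq_len(n_b), each = 8L), times = n_e)
  n_veh <- length(veh_ep)
  veh <- data.frame(
    plate_id = sprintf("P%03d_%02d", veh_ep, veh_b),
    well_id = sprintf("V%07d", seq_len(n_veh)),
    sample_id = "VEHICLE",
    chemical_id = "DMSO",
    concentration_uM = 0,
    endpoint_id = eps[veh_ep],
    raw_value = baseline * 10^stats::rnorm(n_veh, 0, noise_sd),
    well_role = "vehicle_control",
    stringsAsFactors = FALSE
  )

  truth <- build_screen_truth(chem_ids, arch_of_chem, E, vocabulary,
                              concs, ramp, config)
  list(wells = rbind(trt, veh), truth = truth)
}

# ground truth derived deterministically from the planted effect matrix
build_screen_truth <- function(chem_ids, arch_of_chem, E, vocabulary,
                               concs, ramp, config) {
  eps <- colnames(E)
  is_down <- vocabulary$is_down[match(eps, vocabulary$endpoint_id)]
  floor_l10 <- log10(config$coff_floor_fold)
  cyto <- cytotox_endpoints(vocabulary)

  hits <- list(); ct <- list(); sigs <- list()
  for (i in seq_along(chem_ids)) {
    eff <- E[i, ]
    # direction-corrected planted response per endpoint and concentration
    dir_resp <- ifelse(is_down, -eff, eff)
    resp <- outer(dir_resp, ramp)               # endpoints x concentrations
    detect <- resp > floor_l10
    hitc <- as.integer(rowSums(detect) > 0L)
    loec <- apply(detect, 1L, function(d)
      if (any(d)) concs[which(d)[1L]] else NA_real_)
    hits[[i]] <- data.frame(chemical_id = chem_ids[i], endpoint_id = eps,
                            hitc = hitc, loec_uM = loec,
                            row.names = NULL, stringsAsFactors = FALSE)
    cyto_loec <- loec[eps %in% cyto & hitc == 1L]
    ct[[i]] <- data.frame(
      chemical_id = chem_ids[i], concentration = concs,
      n_cytotox = vapply(concs, function(co) sum(cyto_loec <= co), numeric(1)),
      stringsAsFactors = FALSE)
    sigs[[i]] <- truth_signature_summary(eff, vocabulary, concs, ramp, config)
    sigs[[i]]$chemical_id <- chem_ids[i]
  }
  structure(list(
    chemicals = data.frame(chemical_id = chem_ids, archetype = arch_of_chem,
                           stringsAsFactors = FALSE),
    effects = E,
    expected_hits = do.call(rbind, hits),
    expected_cytotox = do.call(rbind, ct),
    expected_signatures = do.call(rbind, sigs)[, c("chemical_id", "signature",
                                                   "status", "min_conc")],
    concentrations = concs, ramp = ramp
  ), class = "screen_truth")
}

# Direct transcription of the nine signature rules for noiseless planted
# profiles: the envelope is degenerate at (0, 0), so "outside" means any
# nonzero value. Kept independent of evaluate_signatures() on purpose.
truth_signature_summary <- function(eff, vocabulary, concs, ramp, config) {
  eps <- names(eff)
  srb <- srb_endpoints(vocabulary)
  endo <- vocabulary$is_endothelial_system[match(srb, vocabulary$endpoint_id)]
  val_at <- function(k) eff * ramp[k]
  flags <- matrix(FALSE, nrow = length(concs), ncol = 9L,
                  dimnames = list(NULL, SIGNATURE_NAMES))
  evaluable <- matrix(TRUE, nrow = length(concs), ncol = 9L,
                      dimnames = list(NULL, SIGNATURE_NAMES))
  for (k in seq_along(concs)) {
    v <- val_at(k)
    outside <- v != 0
    acute <- sum(v[srb] <= -0.3) >= 3 && any(v[srb][endo] <= -0.3)
    flags[k, "acute_toxicity"] <- acute
    if (acute) {
      evaluable[k, setdiff(SIGNATURE_NAMES, "acute_toxicity")] <- FALSE
      next
    }
    flags[k, "liver_toxicity"] <- v["3C:SRB"] <= -0.3
    flags[k, "organ_toxicity"] <- outside["3C:Proliferation"] &&
      v["3C:Proliferation"] < -0.1 && v["3C:SRB"] > -0.3
    flags[k, "immunosuppression"] <-
      (outside["SAg:Proliferation"] && v["SAg:Proliferation"] < -0.1) ||
      (outside["BT:sIgG"] && v["BT:sIgG"] < -0.1 &&
         outside["BT:Proliferation"] && v["BT:Proliferation"] < -0.1) ||
      v["SAg:PBMC Cytotoxicity"] < -0.3 || v["BT:PBMC Cytotoxicity"] < -0.3
    flags[k, "thrombosis"] <- outside["3C:TF"] && v["3C:TF"] > 0.1 &&
      v["3C:SRB"] > -0.3
    flags[k, "skin_irritation"] <- outside["LPS:PGE2"] && v["LPS:PGE2"] > 0.1 &&
      !(outside["LPS:sTNFa"] && v["LPS:sTNFa"] < 0)
    flags[k, "skin_sensitization"] <- outside["HDF3CGF:Collagen III"] &&
      v["HDF3CGF:Collagen III"] < -0.1
    flags[k, "skin_rash"] <- outside["HDF3CGF:VCAM-1"] &&
      v["HDF3CGF:VCAM-1"] > 0.1
    flags[k, "vascular_toxicity"] <- outside["CASM3C:SAA"] &&
      v["CASM3C:SAA"] > 0.1
  }
  top <- max(concs)
  out <- lapply(SIGNATURE_NAMES, function(sig) {
    fl <- concs[flags[, sig] & evaluable[, sig]]
    ev <- concs[evaluable[, sig]]
    if (length(ev) == 0L) {
      data.frame(signature = sig, status = "NA", min_conc = NA_real_)
    } else if (length(fl) >= 2L) {
      data.frame(signature = sig, status = "listed_ge", min_conc = min(fl))
    } else if (length(fl) == 1L && fl == top) {
      data.frame(signature = sig, status = "listed_at_top", min_conc = top)
    } else {
      data.frame(signature = sig, status = "nd", min_conc = NA_real_)
    }
  })
  do.call(rbind, out)
}

#' Generate historical vehicle-control collections
#'
#' Per-endpoint Log10Ratio values for `n_runs` historical experimental
#' runs, `wells_per_run` vehicle wells each, drawn Normal(0, `noise_sd`).
#'
#' @param vocabulary an [endpoint_vocabulary()].
#' @param n_runs historical runs (default 23).
#' @param wells_per_run vehicle wells per run (default 8).
#' @param noise_sd Log10Ratio noise sd.
#' @param seed random seed.
#' @return data.frame `endpoint_id`, `run`, `value`.
#' @export
generate_historical_controls <- function(vocabulary, n_runs = 23L,
                                         wells_per_run = 8L,
                                         noise_sd = 0.05, seed = 1L) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  set.seed(seed)
  n_e <- nrow(vocabulary)
  n <- n_e * n_runs * wells_per_run
  data.frame(
    endpoint_id = rep(vocabulary$endpoint_id, each = n_runs * wells_per_run),
    run = rep(rep(seq_len(n_runs), each = wells_per_run), times = n_e),
    value = stats::rnorm(n, 0, noise_sd),
    stringsAsFactors = FALSE
  )
}

#' Generate a labeled reference profile database
#'
#' Profiles scattered around each archetype's full-effect (top
#' concentration) mean, labeled with the archetype mechanism, for testing
#' the similarity search. Cytotoxicity counts are derived from the planted
#' effects (cytotoxicity-role endpoints at or below -0.3).
#'
#' @param vocabulary an [endpoint_vocabulary()].
#' @param archetypes archetype names to include (default: every archetype
#'   except `inactive`).
#' @param n_per_archetype profiles per archetype.
#' @param noise_sd Log10Ratio noise sd.
#' @param seed random seed.
#' @param concentration nominal screened concentration recorded per
#'   profile.
#' @return a [reference_db()].
#' @export
generate_reference_db <- function(vocabulary, archetypes = NULL,
                                  n_per_archetype = 2L, noise_sd = 0.05,
                                  seed = 1L, concentration = 60) {
  if (is.null(archetypes)) {
    archetypes <- setdiff(names(archetype_specs(vocabulary)), "inactive")
  }
  specs <- archetype_specs(vocabulary, archetypes = archetypes)
  set.seed(seed)
  eps <- vocabulary$endpoint_id
  cyto <- cytotox_endpoints(vocabulary)
  rows <- list(); labels <- character(); mech <- character(); nct <- integer()
  for (a in specs) {
    mu <- stats::setNames(numeric(length(eps)), eps)
    mu[names(a$effects)] <- a$effects
    for (i in seq_len(n_per_archetype)) {
      rows[[length(rows) + 1L]] <- mu + stats::rnorm(length(eps), 0, noise_sd)
      labels <- c(labels, paste0(a$name, ".", i))
      mech <- c(mech, a$name)
      nct <- c(nct, sum(mu[cyto] <= -0.3))
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- eps
  reference_db(values, labels, rep(concentration, length(labels)), nct, mech)
}

#' Simulate positive-control profiles for QC studies
#'
#' Draws profiles around a fixed strong-suppression pattern (total-protein
#' and proliferation endpoints reduced), emulating a cytotoxic on-plate
#' positive control.
#'
#' @param vocabulary an [endpoint_vocabulary()].
#' @param n_profiles number of profiles.
#' @param noise_sd Log10Ratio noise sd.
#' @param seed random seed.
#' @return numeric matrix, one profile per row.
#' @export
simulate_positive_controls <- function(vocabulary, n_profiles,
                                       noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  eps <- vocabulary$endpoint_id
  mu <- stats::setNames(numeric(length(eps)), eps)
  mu[srb_endpoints(vocabulary)] <- -0.4
  mu[endpoints_with_role(vocabulary, c("proliferation", "pbmc_cytotoxicity"))] <- -0.5
  t(vapply(seq_len(n_profiles),
           function(i) mu + stats::rnorm(length(eps), 0, noise_sd),
           numeric(length(eps))))
}
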