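# Shared fixtures: built in code, no files.

FULL_VOCAB <- default_endpoints()

# minimal vocabulary that still satisfies the signature engine
small_vocab <- function() {
  sys <- c("3C", "3C", "3C", "4H", "LPS", "LPS", "LPS", "SAg", "SAg",
           "BT", "BT", "BT", "HDF3CGF", "HDF3CGF", "HDF3CGF",
           "CASM3C", "CASM3C", "BE3C", "Mphg", "Mphg")
  bio <- c("SRB", "Proliferation", "TF", "SRB", "SRB", "PGE2", "sTNFa",
           "Proliferation", "PBMC Cytotoxicity",
           "sIgG", "Proliferation", "PBMC Cytotoxicity",
           "SRB", "Collagen III", "VCAM-1",
           "SRB", "SAA", "SRB", "SRB", "sIL-10")
  roles <- ifelse(bio == "SRB", "srb_total_protein",
           ifelse(bio == "PBMC Cytotoxicity", "pbmc_cytotoxicity",
           ifelse(bio == "Proliferation", "proliferation",
           ifelse(bio == "sIgG", "igg_secretion", "biomarker"))))
  down <- roles != "biomarker" |
    paste0(sys, ":", bio) %in% c("Mphg:sIL-10", "HDF3CGF:Collagen III")
  endpoint_vocabulary(sys, bio, down, roles)
}

# profile matrix from a plain matrix of values over a vocabulary; one row
# per synthetic sample at a single concentration
pm_from_rows <- function(values, vocab = FULL_VOCAB, conc = 60,
                         sample_id = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- vocab$endpoint_id
  if (is.null(sample_id)) sample_id <- sprintf("R%04d", seq_len(nrow(values)))
  profile_matrix(values, sample_id, rep(conc, length.out = nrow(values)),
                 stats::setNames(sample_id, sample_id))
}

# one zero row over a vocabulary with selected endpoints set
profile_row <- function(vocab = FULL_VOCAB, ...) {
  v <- stats::setNames(numeric(nrow(vocab)), vocab$endpoint_id)
  set <- c(...)
  v[names(set)] <- set
  v
}

# symmetric envelope (-half, half) over every endpoint
flat_envelope <- function(vocab = FULL_VOCAB, half = 0.05) {
  data.frame(endpoint_id = vocab$endpoint_id, lower = -half, upper = half,
             stringsAsFactors = FALSE)
}

# tiny well table: one chemical, one sample, one endpoint, 4 concentrations
tiny_wells <- function(raw_treatment = c(100, 100, 100, 100),
                       raw_vehicle = rep(100, 8),
                       endpoint_id = "3C:SRB",
                       concs = c(2.2, 6.7, 20, 60)) {
  trt <- data.frame(plate_id = "P1", well_id = sprintf("W%d", seq_along(concs)),
                    sample_id = "S1", chemical_id = "CHEM1",
                    concentration_uM = concs, endpoint_id = endpoint_id,
                    raw_value = raw_treatment, well_role = "treatment",
                    stringsAsFactors = FALSE)
  veh <- data.frame(plate_id = "P1", well_id = sprintf("V%d", 1:8),
                    sample_id = "VEHICLE", chemical_id = "DMSO",
                    concentration_uM = 0, endpoint_id = endpoint_id,
                    raw_value = raw_vehicle, well_role = "vehicle_control",
                    stringsAsFactors = FALSE)
  rbind(trt, veh)
}
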