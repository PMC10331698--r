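#' Toxicity signature names, in evaluation order
#'
#' The nine rule-based alerts. Acute toxicity is evaluated first and, when
#' flagged, masks all other signatures at that concentration; liver
#' toxicity is the one alert that both flags and lets evaluation continue.
#' @export
SIGNATURE_NAMES <- c("acute_toxicity", "liver_toxicity", "organ_toxicity",
                     "immunosuppression", "thrombosis", "skin_irritation",
                     "skin_sensitization", "skin_rash", "vascular_toxicity")

# endpoints each signature consults, for error reporting
SIGNATURE_ENDPOINTS <- list(
  acute_toxicity = NULL, # all SRB endpoints; resolved from the vocabulary
  liver_toxicity = "3C:SRB",
  organ_toxicity = c("3C:Proliferation", "3C:SRB"),
  immunosuppression = c("SAg:Proliferation", "BT:sIgG", "BT:Proliferation",
                        "SAg:PBMC Cytotoxicity", "BT:PBMC Cytotoxicity"),
  thrombosis = c("3C:TF", "3C:SRB"),
  skin_irritation = c("LPS:PGE2", "LPS:sTNFa"),
  skin_sensitization = "HDF3CGF:Collagen III",
  skin_rash = "HDF3CGF:VCAM-1",
  vascular_toxicity = "CASM3C:SAA"
)

#' Evaluate the nine toxicity signatures
#'
#' Applies the stepwise rule engine to every (sample, concentration) row of
#' an un-inverted Log10Ratio profile matrix. The rules, in order:
#'
#' 1. **Acute toxicity** — three or more SRB endpoints at or below -0.3,
#'    at least one in an endothelial system (3C, 4H, LPS, Mphg). Flagged
#'    concentrations are not evaluated for any other signature
#'    (`evaluable = FALSE`).
#' 2. **Liver toxicity** — `3C:SRB` at or below -0.3; evaluation continues.
#' 3. **Organ toxicity** — `3C:Proliferation` outside the envelope and
#'    below -0.1, with `3C:SRB` above -0.3 (not cytotoxic in that system).
#' 4. **Immunosuppression** — `SAg:Proliferation` outside the envelope and
#'    below -0.1; or `BT:sIgG` and `BT:Proliferation` both outside the
#'    envelope and below -0.1; or PBMC cytotoxicity
#'    (`SAg:PBMC Cytotoxicity` or `BT:PBMC Cytotoxicity` below -0.3).
#' 5. **Thrombosis** — `3C:TF` outside the envelope and above 0.1, with
#'    `3C:SRB` above -0.3.
#' 6. **Skin irritation** — `LPS:PGE2` outside the envelope and above 0.1,
#'    with `LPS:sTNFa` increased or unchanged (not both outside the
#'    envelope and negative).
#' 7. **Skin sensitization** — `HDF3CGF:Collagen III` outside the envelope
#'    and below -0.1.
#' 8. **Skin rash** — `HDF3CGF:VCAM-1` outside the envelope and above 0.1.
#' 9. **Vascular toxicity** — `CASM3C:SAA` outside the envelope and above
#'    0.1.
#'
#' The -0.1/0.1 effect-size bound (a 20% change) and the -0.3 cytotoxicity
#' bound come from `config`; envelope comparisons are strict.
#'
#' @param pm un-inverted [profile_matrix()].
#' @param envelope envelope table from [build_envelope()].
#' @param vocabulary an [endpoint_vocabulary()].
#' @param config a [pipeline_config()].
#' @return data.frame with one row per profile and signature: `sample_id`,
#'   `concentration`, `signature`, `flagged`, `evaluable`.
#' @export
evaluate_signatures <- function(pm, envelope, vocabulary,
                                config = pipeline_config()) {
  required <- unique(c(unlist(SIGNATURE_ENDPOINTS), srb_endpoints(vocabulary)))
  for (sig in names(SIGNATURE_ENDPOINTS)) {
    need <- SIGNATURE_ENDPOINTS[[sig]]
    if (sig == "acute_toxicity") need <- srb_endpoints(vocabulary)
    miss <- setdiff(need, colnames(pm))
    if (length(miss) > 0L) {
      stop("signature ", sig, " requires endpoint(s) missing from the profile: ",
           paste(miss, collapse = ", "))
    }
  }
  miss_env <- setdiff(intersect(required, colnames(pm)), envelope$endpoint_id)
  if (length(miss_env) > 0L) {
    stop("envelope missing required endpoint(s): ",
         paste(miss_env, collapse = ", "))
  }

  v <- unclass(pm)
  cyt <- config$cytotox_log10ratio   # -0.3
  eff <- config$effect_size          # 0.1
  out <- function(ep) outside_envelope(v[, ep], ep, envelope)

  srb <- srb_endpoints(vocabulary)
  srb_endo <- srb[vocabulary$is_endothelial_system[match(srb, vocabulary$endpoint_id)]]
  srb_low <- v[, srb, drop = FALSE] <= cyt
  acute <- rowSums(srb_low) >= 3L &
    rowSums(srb_low[, srb %in% srb_endo, drop = FALSE]) >= 1L

  liver <- v[, "3C:SRB"] <= cyt
  organ <- out("3C:Proliferation") & v[, "3C:Proliferation"] < -eff &
    v[, "3C:SRB"] > cyt
  immuno <- (out("SAg:Proliferation") & v[, "SAg:Proliferation"] < -eff) |
    (out("BT:sIgG") & v[, "BT:sIgG"] < -eff &
       out("BT:Proliferation") & v[, "BT:Proliferation"] < -eff) |
    v[, "SAg:PBMC Cytotoxicity"] < cyt |
    v[, "BT:PBMC Cytotoxicity"] < cyt
  thromb <- out("3C:TF") & v[, "3C:TF"] > eff & v[, "3C:SRB"] > cyt
  tnfa_decreased <- out("LPS:sTNFa") & v[, "LPS:sTNFa"] < 0
  irritation <- out("LPS:PGE2") & v[, "LPS:PGE2"] > eff & !tnfa_decreased
  sensitization <- out("HDF3CGF:Collagen III") &
    v[, "HDF3CGF:Collagen III"] < -eff
  rash <- out("HDF3CGF:VCAM-1") & v[, "HDF3CGF:VCAM-1"] > eff
  vascular <- out("CASM3C:SAA") & v[, "CASM3C:SAA"] > eff

  flags <- cbind(acute_toxicity = acute,
                 liver_toxicity = liver & !acute,
                 organ_toxicity = organ & !acute,
                 immunosuppression = immuno & !acute,
                 thrombosis = thromb & !acute,
                 skin_irritation = irritation & !acute,
                 skin_sensitization = sensitization & !acute,
                 skin_rash = rash & !acute,
                 vascular_toxicity = vascular & !acute)
  evaluable <- cbind(acute_toxicity = rep(TRUE, nrow(v)),
                     matrix(!acute, nrow = nrow(v), ncol = 8L,
                            dimnames = list(NULL, SIGNATURE_NAMES[-1L])))

  n <- nrow(v)
  data.frame(
    sample_id = rep(pm_samples(pm), times = length(SIGNATURE_NAMES)),
    concentration = rep(pm_concs(pm), times = length(SIGNATURE_NAMES)),
    signature = rep(SIGNATURE_NAMES, each = n),
    flagged = as.logical(flags[, SIGNATURE_NAMES]),
    evaluable = as.logical(evaluable[, SIGNATURE_NAMES]),
    stringsAsFactors = FALSE
  )
}

#' Summarize signature calls to the chemical level
#'
#' A concentration counts as flagged for a chemical when **both** duplicate
#' samples are flagged there. The chemical-level status then follows the
#' reporting convention: flagged at two or more concentrations is listed as
#' `>=` the lowest such concentration (`listed_ge`); flagged at the top
#' tested concentration only is listed as that concentration
#' (`listed_at_top`); not flagged at any evaluable concentration is `nd`;
#' no evaluable concentration at all (e.g. acutely cytotoxic everywhere) is
#' `NA`. A flag at exactly one non-top concentration summarizes to `nd`.
#'
#' @param calls signature calls from [evaluate_signatures()].
#' @param replicate_of named character vector mapping sample to chemical.
#' @return data.frame `chemical_id`, `signature`, `status` (one of `nd`,
#'   `NA`, `listed_at_top`, `listed_ge`), `min_conc` (uM, `NA` unless
#'   listed).
#' @export
summarize_signatures <- function(calls, replicate_of) {
  calls$chemical_id <- unname(replicate_of[calls$sample_id])
  if (anyNA(calls$chemical_id)) stop("sample(s) missing from replicate_of")
  out <- list()
  for (chem in unique(calls$chemical_id)) {
    cc <- calls[calls$chemical_id == chem, ]
    top <- max(cc$concentration)
    for (sig in SIGNATURE_NAMES) {
      cs <- cc[cc$signature == sig, ]
      key <- as.character(cs$concentration)
      flagged_all <- tapply(cs$flagged, key, all)
      evaluable_all <- tapply(cs$evaluable, key, all)
      concs <- as.numeric(names(flagged_all))
      fl <- concs[as.logical(flagged_all) & as.logical(evaluable_all)]
      ev <- concs[as.logical(evaluable_all)]
      if (length(ev) == 0L) {
        status <- "NA"; mc <- NA_real_
      } else if (length(fl) >= 2L) {
        status <- "listed_ge"; mc <- min(fl)
      } else if (length(fl) == 1L && fl == top) {
        status <- "listed_at_top"; mc <- top
      } else {
        status <- "nd"; mc <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        chemical_id = chem, signature = sig, status = status,
        min_conc = mc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

render_signature_cell <- function(status, min_conc) {
  ifelse(status == "nd", "nd",
  ifelse(status == "NA", "NA",
  ifelse(status == "listed_at_top", format_conc(min_conc),
         paste0(">=", format_conc(min_conc)))))
}

format_conc <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, digits = 7)
}

#' Render and parse the chemical-by-signature summary table
#'
#' One row per chemical, one column per signature; cells are `"nd"`,
#' `"NA"`, a bare concentration (flag at the top tested concentration
#' only), or `">=conc"` (flag at two or more concentrations, listed at the
#' lowest).
#'
#' @param summaries output of [summarize_signatures()].
#' @return `signature_table()`: data.frame, chemicals by signatures.
#' @export
signature_table <- function(summaries) {
  chems <- unique(summaries$chemical_id)
  tab <- data.frame(chemical_id = chems, stringsAsFactors = FALSE)
  for (sig in SIGNATURE_NAMES) {
    s <- summaries[summaries$signature == sig, ]
    s <- s[match(chems, s$chemical_id), ]
    tab[[sig]] <- render_signature_cell(s$status, s$min_conc)
  }
  tab
}

#' @rdname signature_table
#' @param tab a rendered signature table.
#' @return `parse_signature_table()`: the `summaries` data.frame back.
#' @export
parse_signature_table <- function(tab) {
  out <- list()
  for (i in seq_len(nrow(tab))) {
    for (sig in SIGNATURE_NAMES) {
      cell <- as.character(tab[[sig]][i])
      if (is.na(cell) || cell == "NA") {
        status <- "NA"; mc <- NA_real_
      } else if (cell == "nd") {
        status <- "nd"; mc <- NA_real_
      } else if (startsWith(cell, ">=")) {
        status <- "listed_ge"; mc <- as.numeric(substring(cell, 3L))
      } else {
        status <- "listed_at_top"; mc <- as.numeric(cell)
      }
      out[[length(out) + 1L]] <- data.frame(
        chemical_id = tab$chemical_id[i], signature = sig,
        status = status, min_conc = mc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @rdname signature_table
#' @param path file path for CSV output.
#' @export
write_signature_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
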