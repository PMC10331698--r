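#' Overt cytotoxicity flags
#'
#' A sample-concentration profile is overtly cytotoxic when any
#' cytotoxicity-role endpoint (SRB total protein or PBMC viability) falls
#' below the -0.3 Log10Ratio threshold on the un-inverted scale. The
#' comparison is strict (`<`) by default; the signature engine applies its
#' own printed comparisons separately and the two notions are never
#' conflated.
#'
#' @param pm un-inverted [profile_matrix()].
#' @param vocabulary an [endpoint_vocabulary()].
#' @param threshold Log10Ratio threshold (default -0.3).
#' @param strict strict `<` (default) or `<=`.
#' @return data.frame with one row per profile: `sample_id`,
#'   `concentration`, `overt`, `cytotox_endpoints_below` (semicolon-joined
#'   endpoint ids).
#' @export
flag_overt <- function(pm, vocabulary, threshold = -0.3, strict = TRUE) {
  cyto <- intersect(cytotox_endpoints(vocabulary), colnames(pm))
  v <- unclass(pm)[, cyto, drop = FALSE]
  below <- if (strict) v < threshold else v <= threshold
  data.frame(
    sample_id = pm_samples(pm),
    concentration = pm_concs(pm),
    overt = rowSums(below) > 0L,
    cytotox_endpoints_below = apply(below, 1L, function(b)
      paste(cyto[b], collapse = ";")),
    stringsAsFactors = FALSE
  )
}

#' Count positive cytotoxicity endpoints at a concentration
#'
#' Number of cytotoxicity-role endpoints a sample is active on (hitc = 1)
#' with LOEC at or below the queried concentration.
#'
#' @param hits hit-call table ([hitcall_table()]) rows for one sample, or a
#'   full table together with `sample_id`.
#' @param vocabulary an [endpoint_vocabulary()].
#' @param concentration query concentration (uM).
#' @param sample_id optional sample filter when `hits` holds many samples.
#' @return integer count.
#' @export
count_active_cytotox <- function(hits, vocabulary, concentration,
                                 sample_id = NULL) {
  if (!is.null(sample_id)) hits <- hits[hits$sample_id %in% sample_id, ]
  cyto <- cytotox_endpoints(vocabulary)
  h <- hits[hits$endpoint_id %in% cyto & hits$hitc == 1L, ]
  sum(!is.na(h$loec_uM) & h$loec_uM <= concentration)
}

#' Per-profile cytotoxicity-endpoint counts
#'
#' Vectorized [count_active_cytotox()] over every (sample, concentration)
#' row of a profile matrix.
#'
#' @param pm a [profile_matrix()] defining the profiles to annotate.
#' @param hits hit-call table from [hitcall_table()].
#' @param vocabulary an [endpoint_vocabulary()].
#' @return data.frame `sample_id`, `concentration`, `n_cytotox`.
#' @export
cytotox_counts <- function(pm, hits, vocabulary) {
  cyto <- cytotox_endpoints(vocabulary)
  h <- hits[hits$endpoint_id %in% cyto & hits$hitc == 1L & !is.na(hits$loec_uM), ]
  loec_by_sample <- split(h$loec_uM, h$sample_id)
  s <- pm_samples(pm)
  co <- pm_concs(pm)
  n <- vapply(seq_along(s), function(i) {
    l <- loec_by_sample[[s[i]]]
    if (is.null(l)) 0L else sum(l <= co[i])
  }, integer(1))
  data.frame(sample_id = s, concentration = co, n_cytotox = n,
             stringsAsFactors = FALSE)
}

#' Nonspecific cytotoxicity
#'
#' A sample is nonspecifically cytotoxic when it is active on
#' `min_endpoints` (default 2) or more cytotoxicity-role endpoints. The
#' reported active concentrations are those at which the running count
#' reaches `min_endpoints`.
#'
#' @param hits hit-call table rows of one sample.
#' @param vocabulary an [endpoint_vocabulary()].
#' @param concentrations tested concentrations of the sample.
#' @param min_endpoints threshold count (default 2).
#' @return list with `nonspecific` (logical) and `active_concentrations`.
#' @export
flag_nonspecific <- function(hits, vocabulary, concentrations,
                             min_endpoints = 2L) {
  counts <- vapply(concentrations, function(co)
    count_active_cytotox(hits, vocabulary, co), integer(1))
  list(nonspecific = any(counts >= min_endpoints),
       active_concentrations = concentrations[counts >= min_endpoints])
}

#' Chemical-level cytotoxicity summary
#'
#' Replicate-averaged counts of positive cytotoxicity endpoints per
#' chemical and concentration (fractional values arise when the duplicate
#' samples disagree), with overt and nonspecific flags. Rows with a zero
#' mean count are dropped.
#'
#' @param pm un-inverted [profile_matrix()].
#' @param hits hit-call table from [hitcall_table()].
#' @param vocabulary an [endpoint_vocabulary()].
#' @param config a [pipeline_config()].
#' @return data.frame `chemical_id`, `concentration`, `mean_n_cytotox`,
#'   `overt`, `nonspecific`.
#' @export
cytotox_summary <- function(pm, hits, vocabulary, config = pipeline_config()) {
  counts <- cytotox_counts(pm, hits, vocabulary)
  counts$chemical_id <- pm_chemicals(pm)
  ov <- flag_overt(pm, vocabulary, config$cytotox_log10ratio,
                   strict = config$overt_strict)
  key <- paste(counts$chemical_id, counts$concentration, sep = "\r")
  mean_n <- tapply(counts$n_cytotox, key, mean)
  any_overt <- tapply(ov$overt, key, any)
  parts <- do.call(rbind, strsplit(names(mean_n), "\r", fixed = TRUE))
  out <- data.frame(chemical_id = parts[, 1L],
                    concentration = as.numeric(parts[, 2L]),
                    mean_n_cytotox = as.numeric(mean_n),
                    overt = as.logical(any_overt),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$nonspecific <- out$mean_n_cytotox >= config$nonspecific_cytotox_min
  out <- out[out$mean_n_cytotox > 0, ]
  out[order(out$chemical_id, out$concentration), ]
}

#' Remove heavily cytotoxic profiles before clustering/similarity
#'
#' Drops profile rows whose positive-cytotoxicity-endpoint count exceeds
#' `max_allowed` (default 2).
#'
#' @param pm a [profile_matrix()].
#' @param counts per-profile counts from [cytotox_counts()].
#' @param max_allowed maximum count retained.
#' @return the filtered [profile_matrix()].
#' @export
filter_for_profiling <- function(pm, counts, max_allowed = 2L) {
  key_pm <- paste(pm_samples(pm), pm_concs(pm), sep = "\r")
  key_ct <- paste(counts$sample_id, counts$concentration, sep = "\r")
  n <- counts$n_cytotox[match(key_pm, key_ct)]
  if (anyNA(n)) stop("cytotoxicity counts missing for some profiles")
  pm[n <= max_allowed, , drop = FALSE]
}
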