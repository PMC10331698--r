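#' Plate %CV of vehicle-control wells
#'
#' 100 * sample sd / mean of the raw vehicle values; scale invariant.
#'
#' @param values raw vehicle-well values of one plate/endpoint (>= 2).
#' @return percent CV.
#' @export
plate_cv <- function(values) {
  if (length(values) < 2L) stop("need >= 2 vehicle wells for a CV")
  100 * stats::sd(values) / mean(values)
}

#' Per-plate vehicle %CV table
#'
#' Computes the %CV per (plate, endpoint) and aggregates to one value per
#' plate by the maximum across endpoints (conservative).
#'
#' @param wells a well table (see [read_well_table()]).
#' @param aggregate `"max"` (default) or `"none"` for per-endpoint rows.
#' @return data.frame `plate_id` (and `endpoint_id` when not aggregated),
#'   `cv_percent`.
#' @export
plate_cv_table <- function(wells, aggregate = c("max", "none")) {
  aggregate <- match.arg(aggregate)
  veh <- wells[wells$well_role == "vehicle_control", ]
  key <- paste(veh$plate_id, veh$endpoint_id, sep = "\r")
  cv <- tapply(veh$raw_value, key, plate_cv)
  parts <- do.call(rbind, strsplit(names(cv), "\r", fixed = TRUE))
  tab <- data.frame(plate_id = parts[, 1L], endpoint_id = parts[, 2L],
                    cv_percent = as.numeric(cv),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (aggregate == "none") return(tab)
  agg <- tapply(tab$cv_percent, tab$plate_id, max)
  data.frame(plate_id = names(agg), cv_percent = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 1% false-negative Pearson cutoff from positive-control references
#'
#' For each reference positive-control profile, computes the Pearson
#' correlation between that profile and the mean of the remaining
#' reference profiles (one leave-one-out value per profile). The cutoff is
#' the empirical 1st percentile of these correlations (linear
#' interpolation between order statistics).
#'
#' @param reference numeric matrix, one positive-control profile per row.
#' @param percentile false-negative percentile (default 0.01).
#' @return list with `cutoff_r` and the vector of `loo_r` values.
#' @export
pearson_fn_cutoff <- function(reference, percentile = 0.01) {
  reference <- as.matrix(reference)
  n <- nrow(reference)
  if (n < 3L) stop("need >= 3 reference positive-control profiles")
  loo_r <- vapply(seq_len(n), function(i) {
    others <- colMeans(reference[-i, , drop = FALSE])
    if (stats::sd(others) == 0 || stats::sd(reference[i, ]) == 0) {
      stop("undefined correlation: constant profile in reference set")
    }
    stats::cor(reference[i, ], others)
  }, numeric(1))
  list(cutoff_r = stats::quantile(loo_r, probs = percentile,
                                  names = FALSE, type = 7),
       loo_r = loo_r)
}

#' Assay acceptance decision
#'
#' A new positive-control profile passes the Pearson test when its
#' correlation with the mean reference profile strictly exceeds the 1%
#' false-negative cutoff. The assay as a whole is accepted when the
#' positive control passes and at least 95% of plates have vehicle
#' %CV < 20.
#'
#' @param new_profile numeric positive-control profile.
#' @param reference matrix of reference positive-control profiles.
#' @param plate_cvs numeric vector of per-plate %CV values.
#' @param cv_limit plate %CV threshold (default 20).
#' @param plate_pass_fraction required fraction of passing plates
#'   (default 0.95).
#' @return list with `pearson_r`, `cutoff_r`, `pearson_pass`,
#'   `plate_pass_fraction_observed`, `plates_pass`, `accept`.
#' @export
qc_accept <- function(new_profile, reference, plate_cvs,
                      cv_limit = 20, plate_pass_fraction = 0.95) {
  cut <- pearson_fn_cutoff(reference)
  ref_mean <- colMeans(as.matrix(reference))
  r <- stats::cor(new_profile, ref_mean)
  frac <- mean(plate_cvs < cv_limit)
  pearson_pass <- r > cut$cutoff_r
  plates_pass <- frac >= plate_pass_fraction
  list(pearson_r = r, cutoff_r = cut$cutoff_r, pearson_pass = pearson_pass,
       plate_pass_fraction_observed = frac, plates_pass = plates_pass,
       accept = pearson_pass && plates_pass)
}
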