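#' Vehicle-normalized log10 fold-change profiles
#'
#' Each treatment well's raw value is divided by the mean of the 8 vehicle
#' control wells on the same plate for the same endpoint, then log10
#' transformed. Vehicle wells themselves are excluded from the output; the
#' result is a [profile_matrix()] with one row per (sample, concentration).
#'
#' @param wells a validated well table (see [read_well_table()]).
#' @param vocabulary an [endpoint_vocabulary()]; its endpoint order fixes
#'   the column order of the result.
#' @param roles which `well_role` values become output rows (default
#'   `"treatment"`; pass `"positive_control"` to normalize control profiles
#'   the same way).
#' @return A [profile_matrix()] of Log10Ratio values.
#' @export
compute_log10_ratios <- function(wells, vocabulary, roles = "treatment") {
  veh <- wells[wells$well_role == "vehicle_control", ]
  key_veh <- paste(veh$plate_id, veh$endpoint_id, sep = "\r")
  vmean <- tapply(veh$raw_value, key_veh, mean)

  trt <- wells[wells$well_role %in% roles, ]
  if (nrow(trt) == 0L) stop("no wells with role(s) ", paste(roles, collapse = ", "))
  key_trt <- paste(trt$plate_id, trt$endpoint_id, sep = "\r")
  vm <- vmean[key_trt]
  if (anyNA(vm)) {
    miss <- trt[is.na(vm), c("plate_id", "endpoint_id")][1L, ]
    stop("missing vehicle wells for plate ", miss$plate_id,
         " endpoint ", miss$endpoint_id)
  }
  ratio <- log10(trt$raw_value / as.numeric(vm))

  row_key <- paste(trt$sample_id, trt$concentration_uM, sep = "\r")
  rows <- unique(data.frame(key = row_key, sample_id = trt$sample_id,
                            concentration = trt$concentration_uM,
                            stringsAsFactors = FALSE))
  rows <- rows[order(rows$sample_id, rows$concentration), ]
  eps <- vocabulary$endpoint_id
  values <- matrix(NA_real_, nrow = nrow(rows), ncol = length(eps),
                   dimnames = list(NULL, eps))
  values[cbind(match(row_key, rows$key), match(trt$endpoint_id, eps))] <- ratio
  if (anyNA(values)) {
    # tolerate panels narrower than the vocabulary, but not ragged rows
    full <- colSums(is.na(values)) == 0L
    if (!all(colSums(is.na(values)) %in% c(0L, nrow(values)))) {
      stop("ragged well table: some sample-concentration rows lack endpoints")
    }
    values <- values[, full, drop = FALSE]
  }
  rep_of <- tapply(trt$chemical_id, trt$sample_id, `[`, 1L)
  profile_matrix(values, rows$sample_id, rows$concentration,
                 stats::setNames(as.character(rep_of), names(rep_of)))
}

#' Invert loss-of-signal endpoints
#'
#' Negates the columns of down-readout endpoints so that every detectable
#' response points in the positive direction, as hit calling expects. The
#' signature engine consumes the un-inverted matrix; both orientations are
#' therefore kept by the pipeline.
#'
#' @param pm a [profile_matrix()].
#' @param vocabulary an [endpoint_vocabulary()] marking `is_down`.
#' @return A [profile_matrix()] with down columns negated.
#' @export
invert_down_endpoints <- function(pm, vocabulary) {
  down <- vocabulary$endpoint_id[vocabulary$is_down]
  flip <- colnames(pm) %in% down
  out <- unclass(pm)
  out[, flip] <- -out[, flip]
  profile_matrix(out, pm_samples(pm), pm_concs(pm), attr(pm, "replicate_of"))
}

#' Historical-control significance envelope
#'
#' Per-endpoint interval containing the configured fraction (default 95%)
#' of historical vehicle-control Log10Ratios. The default estimator is the
#' empirical quantile pair at (1-coverage)/2 and 1-(1-coverage)/2; the
#' `"normal"` method uses mean +/- z * sd. Bounds are clamped to contain 0
#' (vehicle-centered by construction).
#'
#' @param historical data.frame with columns `endpoint_id` and `value`
#'   (pooled historical vehicle Log10Ratios), or a named list of numeric
#'   vectors.
#' @param coverage envelope coverage in (0, 1).
#' @param method `"quantile"` or `"normal"`.
#' @return data.frame with columns `endpoint_id`, `lower`, `upper`.
#' @export
build_envelope <- function(historical, coverage = 0.95,
                           method = c("quantile", "normal")) {
  method <- match.arg(method)
  if (is.list(historical) && !is.data.frame(historical)) {
    historical <- data.frame(
      endpoint_id = rep(names(historical), lengths(historical)),
      value = unlist(historical, use.names = FALSE))
  }
  if (coverage <= 0 || coverage >= 1) stop("coverage must lie in (0, 1)")
  vals <- split(historical$value, historical$endpoint_id)
  short <- names(vals)[lengths(vals) < 2L]
  if (length(short) > 0L) {
    stop("need >= 2 historical values per endpoint; too few for: ",
         paste(short, collapse = ", "))
  }
  alpha <- (1 - coverage) / 2
  bounds <- vapply(vals, function(v) {
    if (method == "quantile") {
      stats::quantile(v, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
    } else {
      z <- stats::qnorm(1 - alpha)
      mean(v) + c(-1, 1) * z * stats::sd(v)
    }
  }, numeric(2))
  data.frame(endpoint_id = colnames(bounds),
             lower = pmin(bounds[1L, ], 0),
             upper = pmax(bounds[2L, ], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Is a value outside the historical envelope?
#'
#' Strict comparison: values exactly on a bound are inside.
#'
#' @param value numeric Log10Ratio value(s).
#' @param endpoint_id endpoint id(s), recycled against `value`.
#' @param envelope envelope table from [build_envelope()].
#' @return logical vector.
#' @export
outside_envelope <- function(value, endpoint_id, envelope) {
  idx <- match(endpoint_id, envelope$endpoint_id)
  if (anyNA(idx)) {
    stop("endpoint(s) absent from envelope: ",
         paste(unique(endpoint_id[is.na(idx)]), collapse = ", "))
  }
  value < envelope$lower[idx] | value > envelope$upper[idx]
}
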