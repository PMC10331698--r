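#' Pipeline configuration
#'
#' Collects every tunable threshold of the profiling pipeline in one
#' validated object. Defaults reproduce the standard analysis: a -0.3
#' Log10Ratio overt-cytotoxicity threshold, a 1.2-fold response-cutoff floor,
#' a 95% historical-control envelope, Pearson similarity reported above
#' r = 0.6 (top 10), profiles with more than 2 positive cytotoxicity
#' endpoints excluded from clustering/similarity, and nonspecific
#' cytotoxicity at 2 or more active cytotoxicity endpoints.
#'
#' @param cytotox_log10ratio overt-cytotoxicity threshold on Log10Ratio.
#' @param effect_size minimum effect size (|Log10Ratio|) for the
#'   envelope-based signature rules; 0.1 corresponds to a 20% change.
#' @param coff_floor_fold fold-change floor of the hit-call cutoff; the
#'   cutoff is `max(3 * bmad, log10(coff_floor_fold))`.
#' @param envelope_coverage coverage of the historical-control envelope.
#' @param envelope_method `"quantile"` (empirical, default) or `"normal"`
#'   (normal-theory interval).
#' @param similarity_r_min,similarity_top_k Pearson search thresholds.
#' @param max_cytotox_endpoints_for_profiling profiles with more positive
#'   cytotoxicity endpoints than this are dropped before clustering and
#'   similarity search.
#' @param nonspecific_cytotox_min active cytotoxicity endpoints needed to
#'   call a sample nonspecifically cytotoxic.
#' @param overt_strict if `TRUE` (default) overt cytotoxicity uses a strict
#'   `<` comparison against `cytotox_log10ratio`; the signature engine keeps
#'   its own printed comparisons regardless.
#' @param mad_constant scale constant of the median absolute deviation
#'   (1.4826 for consistency with the normal sd; set 1 for the raw MAD).
#' @param concentrations default test-concentration series in uM.
#' @param noise_sd default measurement noise (Log10Ratio units) of the
#'   synthetic generator.
#' @param som_grid_full,som_grid_filtered SOM grid dimensions (rows, cols)
#'   for the full and cytotoxicity-filtered clustering passes.
#' @param som_epochs batch-SOM training epochs.
#' @param batch_size chemicals per simulated plate batch.
#' @param seed default random seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cytotox_log10ratio = -0.3,
                            effect_size = 0.1,
                            coff_floor_fold = 1.2,
                            envelope_coverage = 0.95,
                            envelope_method = c("quantile", "normal"),
                            similarity_r_min = 0.6,
                            similarity_top_k = 10,
                            max_cytotox_endpoints_for_profiling = 2,
                            nonspecific_cytotox_min = 2,
                            overt_strict = TRUE,
                            mad_constant = 1.4826,
                            concentrations = c(2.2, 6.7, 20, 60),
                            noise_sd = 0.05,
                            som_grid_full = c(7, 7),
                            som_grid_filtered = c(6, 6),
                            som_epochs = 100,
                            batch_size = 12,
                            seed = 1L) {
  envelope_method <- match.arg(envelope_method)
  cfg <- list(
    cytotox_log10ratio = cytotox_log10ratio,
    effect_size = effect_size,
    coff_floor_fold = coff_floor_fold,
    envelope_coverage = envelope_coverage,
    envelope_method = envelope_method,
    similarity_r_min = similarity_r_min,
    similarity_top_k = as.integer(similarity_top_k),
    max_cytotox_endpoints_for_profiling = max_cytotox_endpoints_for_profiling,
    nonspecific_cytotox_min = nonspecific_cytotox_min,
    overt_strict = isTRUE(overt_strict),
    mad_constant = mad_constant,
    concentrations = sort(concentrations),
    noise_sd = noise_sd,
    som_grid_full = as.integer(som_grid_full),
    som_grid_filtered = as.integer(som_grid_filtered),
    som_epochs = as.integer(som_epochs),
    batch_size = as.integer(batch_size),
    seed = as.integer(seed)
  )
  num <- unlist(cfg[c("cytotox_log10ratio", "effect_size", "coff_floor_fold",
                      "envelope_coverage", "similarity_r_min", "noise_sd",
                      "mad_constant", "concentrations")])
  if (!all(is.finite(num))) stop("all thresholds must be finite")
  if (cfg$envelope_coverage <= 0 || cfg$envelope_coverage >= 1) {
    stop("envelope_coverage must lie in (0, 1)")
  }
  if (cfg$coff_floor_fold <= 1) stop("coff_floor_fold must exceed 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(cfg$concentrations <= 0)) stop("concentrations must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-36s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
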