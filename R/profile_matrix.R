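#' Profile matrix of Log10Ratio responses
#'
#' A numeric matrix with one row per (sample, concentration) pair and one
#' column per endpoint, holding log10 fold-change values relative to
#' same-plate vehicle controls. Row metadata (sample ids, concentrations and
#' the sample-to-chemical map) travels with the matrix so that subsetting
#' rows keeps the bookkeeping consistent.
#'
#' @param values numeric matrix, columns named by endpoint id.
#' @param sample_id character vector, one per row.
#' @param concentration numeric vector (uM), one per row.
#' @param replicate_of named character vector mapping `sample_id` to
#'   `chemical_id` (blinded duplicate samples of one chemical carry distinct
#'   sample ids).
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(values, sample_id, concentration, replicate_of) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(sample_id),
            nrow(values) == length(concentration),
            !is.null(colnames(values)))
  if (!all(is.finite(values))) stop("profile values must all be finite")
  if (is.null(names(replicate_of))) stop("replicate_of must be named by sample_id")
  rownames(values) <- paste0(sample_id, ":", concentration)
  structure(values,
            sample_id = as.character(sample_id),
            concentration = as.numeric(concentration),
            replicate_of = replicate_of,
            class = c("profile_matrix", "matrix", "array"))
}

#' Row metadata accessors
#' @param x a `profile_matrix`.
#' @return `pm_samples()` and `pm_concs()` return per-row vectors;
#'   `pm_chemicals()` returns the chemical id of each row.
#' @export
pm_samples <- function(x) attr(x, "sample_id")

#' @rdname pm_samples
#' @export
pm_concs <- function(x) attr(x, "concentration")

#' @rdname pm_samples
#' @export
pm_chemicals <- function(x) unname(attr(x, "replicate_of")[pm_samples(x)])

#' @export
`[.profile_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, drop = drop]
  if (is.matrix(out)) {
    keep <- if (missing(i)) seq_len(nrow(x)) else seq_len(nrow(x))[i]
    structure(out,
              sample_id = attr(x, "sample_id")[keep],
              concentration = attr(x, "concentration")[keep],
              replicate_of = attr(x, "replicate_of"),
              class = class(x))
  } else {
    out
  }
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d profiles x %d endpoints (%d samples, %d chemicals)\n",
              nrow(x), ncol(x), length(unique(pm_samples(x))),
              length(unique(attr(x, "replicate_of")))))
  invisible(x)
}
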