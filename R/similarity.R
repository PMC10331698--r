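#' Pearson correlation between two response profiles
#'
#' Computed over the endpoints the two profiles share (matched by name when
#' both vectors are named). Requires at least 3 shared endpoints and two
#' non-constant vectors.
#'
#' @param a,b numeric Log10Ratio vectors, named by endpoint id.
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_profile <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]; b <- b[shared]
  }
  if (length(a) != length(b)) stop("profiles have different lengths")
  if (length(a) < 3L) stop("need at least 3 shared endpoints")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant profile")
  }
  stats::cor(a, b)
}

#' Reference profile database
#'
#' A labeled matrix of reference Log10Ratio profiles with per-profile
#' metadata: the mechanism label, the screened concentration, and the
#' number of positive cytotoxicity endpoints (used to exclude cytotoxic
#' profiles from the search).
#'
#' @param values numeric matrix, one reference profile per row, columns
#'   named by endpoint id.
#' @param label character mechanism/chemical label per row (unique).
#' @param concentration screened concentration (uM) per row.
#' @param n_cytotox positive-cytotoxicity-endpoint count per row.
#' @param mechanism optional mechanism class per row (defaults to `label`).
#' @return object of class `reference_db`.
#' @export
reference_db <- function(values, label, concentration, n_cytotox,
                         mechanism = label) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(label),
            nrow(values) == length(concentration),
            nrow(values) == length(n_cytotox))
  if (anyDuplicated(label)) stop("reference labels must be unique")
  rownames(values) <- label
  structure(list(values = values, label = label,
                 concentration = as.numeric(concentration),
                 n_cytotox = as.integer(n_cytotox),
                 mechanism = mechanism),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d profiles x %d endpoints, %d mechanisms\n",
              nrow(x$values), ncol(x$values), length(unique(x$mechanism))))
  invisible(x)
}

#' Search a reference database for similar profiles
#'
#' Ranks reference profiles by Pearson correlation with the query, keeps
#' correlations strictly above `r_min`, and returns at most `top_k`
#' matches in descending r (ties broken by label, for determinism).
#' Cytotoxic reference profiles (more than `max_cytotox` positive
#' cytotoxicity endpoints) are excluded by default, as heavy cytotoxicity
#' yields profile similarity that confounds mechanistic interpretation.
#' Queries sharing fewer than half of the reference endpoints are rejected
#' with a warning (an empty result).
#'
#' @param query named numeric Log10Ratio vector.
#' @param db a [reference_db()].
#' @param r_min minimum correlation (strict; default 0.6).
#' @param top_k maximum matches returned (default 10).
#' @param exclude_cytotoxic drop references with `n_cytotox > max_cytotox`.
#' @param max_cytotox cytotoxicity-endpoint bound for the exclusion.
#' @return data.frame `label`, `mechanism`, `concentration`, `r`, `rank`.
#' @export
search_reference <- function(query, db, r_min = 0.6, top_k = 10L,
                             exclude_cytotoxic = TRUE, max_cytotox = 2L) {
  shared <- intersect(names(query), colnames(db$values))
  if (length(shared) < 0.5 * ncol(db$values)) {
    warning("query shares fewer than half of the reference endpoints; no matches returned")
    return(empty_matches())
  }
  keep <- rep(TRUE, nrow(db$values))
  if (exclude_cytotoxic) keep <- db$n_cytotox <= max_cytotox
  if (!any(keep)) return(empty_matches())

  q <- query[shared]
  m <- db$values[keep, shared, drop = FALSE]
  ok <- apply(m, 1L, stats::sd) > 0
  r <- rep(NA_real_, nrow(m))
  if (stats::sd(q) > 0 && any(ok)) {
    r[ok] <- as.numeric(stats::cor(q, t(m[ok, , drop = FALSE])))
  }
  res <- data.frame(label = db$label[keep], mechanism = db$mechanism[keep],
                    concentration = db$concentration[keep], r = r,
                    stringsAsFactors = FALSE)
  res <- res[!is.na(res$r) & res$r > r_min, ]
  if (nrow(res) == 0L) return(empty_matches())
  res <- res[order(-res$r, res$label), ]
  res <- utils::head(res, top_k)
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

empty_matches <- function() {
  data.frame(label = character(), mechanism = character(),
             concentration = numeric(), r = numeric(), rank = integer(),
             stringsAsFactors = FALSE)
}

#' Batch similarity search over a profile matrix
#'
#' Runs [search_reference()] for every row of a (typically
#' cytotoxicity-filtered) profile matrix.
#'
#' @param pm a [profile_matrix()].
#' @param db a [reference_db()].
#' @param config a [pipeline_config()] supplying `similarity_r_min`,
#'   `similarity_top_k` and `max_cytotox_endpoints_for_profiling`.
#' @return data.frame of matches with `sample_id` and `concentration`
#'   columns prepended.
#' @export
similarity_table <- function(pm, db, config = pipeline_config()) {
  out <- list()
  v <- unclass(pm)
  for (i in seq_len(nrow(v))) {
    res <- search_reference(v[i, ], db,
                            r_min = config$similarity_r_min,
                            top_k = config$similarity_top_k,
                            max_cytotox = config$max_cytotox_endpoints_for_profiling)
    if (nrow(res) > 0L) {
      out[[length(out) + 1L]] <- cbind(
        data.frame(sample_id = pm_samples(pm)[i],
                   concentration = pm_concs(pm)[i],
                   stringsAsFactors = FALSE),
        res)
    }
  }
  if (length(out) == 0L) {
    return(cbind(data.frame(sample_id = character(), concentration = numeric()),
                 empty_matches()))
  }
  do.call(rbind, out)
}
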