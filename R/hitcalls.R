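#' Baseline median absolute deviation (bmad)
#'
#' The baseline variability of an endpoint is the scaled median absolute
#' deviation of the direction-corrected responses pooled over every sample's
#' two lowest tested concentrations — a conservative estimate of sampling
#' noise, since planted or real effects concentrate at the higher
#' concentrations. Samples tested at a single concentration contribute that
#' concentration.
#'
#' @param pm direction-corrected [profile_matrix()] (see
#'   [invert_down_endpoints()]).
#' @param endpoint_id endpoint to compute; `compute_bmad_all()` returns the
#'   named vector for every column.
#' @param constant MAD scale constant (default 1.4826, consistent with the
#'   normal sd).
#' @return bmad in Log10Ratio units.
#' @export
compute_bmad <- function(pm, endpoint_id, constant = 1.4826) {
  if (!endpoint_id %in% colnames(pm)) stop("unknown endpoint: ", endpoint_id)
  pool <- unclass(pm)[baseline_rows(pm), endpoint_id]
  pool <- pool[!is.na(pool)]
  if (length(pool) == 0L) stop("empty baseline pool for ", endpoint_id)
  stats::mad(pool, constant = constant)
}

#' @rdname compute_bmad
#' @export
compute_bmad_all <- function(pm, constant = 1.4826) {
  rows <- baseline_rows(pm)
  if (!any(rows)) stop("empty baseline pool")
  apply(unclass(pm)[rows, , drop = FALSE], 2L,
        stats::mad, constant = constant)
}

# logical mask of rows at each sample's two lowest tested concentrations
baseline_rows <- function(pm) {
  s <- pm_samples(pm)
  co <- pm_concs(pm)
  mask <- logical(length(s))
  for (ss in unique(s)) {
    i <- which(s == ss)
    low <- utils::head(sort(unique(co[i])), 2L)
    mask[i[co[i] %in% low]] <- TRUE
  }
  mask
}

#' Response cutoff for a positive hit call
#'
#' `max(3 * bmad, log10(floor_fold))`; the floor guards against
#' unrealistically tight cutoffs when the baseline is very quiet.
#'
#' @param bmad baseline MAD (Log10Ratio units), `>= 0`.
#' @param floor_fold fold-change floor (default 1.2; must exceed 1).
#' @return cutoff in Log10Ratio units.
#' @export
compute_cutoff <- function(bmad, floor_fold = 1.2) {
  if (any(floor_fold <= 1)) stop("floor_fold must exceed 1")
  if (any(bmad < 0)) stop("bmad must be >= 0")
  pmax(3 * bmad, log10(floor_fold))
}

#' Hit call and lowest effective concentration for one response series
#'
#' A sample is active on an endpoint (hitc = 1) when its direction-corrected
#' response strictly exceeds the cutoff at any tested concentration; the
#' LOEC is the lowest such concentration. Ties at the cutoff are inactive.
#'
#' @param responses direction-corrected Log10Ratio responses.
#' @param concentrations matching tested concentrations (uM).
#' @param coff response cutoff from [compute_cutoff()].
#' @return list with elements `hitc` (0/1) and `loec` (uM, `NA` when
#'   `hitc = 0`).
#' @export
call_hits <- function(responses, concentrations, coff) {
  stopifnot(length(responses) == length(concentrations))
  exceeds <- responses > coff
  if (any(exceeds)) {
    list(hitc = 1L, loec = min(concentrations[exceeds]))
  } else {
    list(hitc = 0L, loec = NA_real_)
  }
}

#' Full hit-call table over a profile matrix
#'
#' Computes per-endpoint bmad and cutoff, then calls every sample
#' independently on every endpoint (blinded duplicates stay separate).
#'
#' @param pm direction-corrected [profile_matrix()].
#' @param config a [pipeline_config()].
#' @return data.frame with one row per sample-endpoint: `sample_id`,
#'   `chemical_id`, `endpoint_id`, `bmad`, `coff`, `hitc`, `loec_uM`.
#' @export
hitcall_table <- function(pm, config = pipeline_config()) {
  bmad <- compute_bmad_all(pm, constant = config$mad_constant)
  coff <- compute_cutoff(bmad, config$coff_floor_fold)
  samples <- pm_samples(pm)
  concs <- pm_concs(pm)
  usamp <- unique(samples)
  idx_by_sample <- split(seq_along(samples), samples)[usamp]
  eps <- colnames(pm)
  vals <- unclass(pm)

  n <- length(usamp) * length(eps)
  res <- data.frame(
    sample_id = rep(usamp, each = length(eps)),
    endpoint_id = rep(eps, times = length(usamp)),
    bmad = rep(unname(bmad), times = length(usamp)),
    coff = rep(unname(coff), times = length(usamp)),
    hitc = integer(n), loec_uM = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  hit <- matrix(0L, nrow = length(usamp), ncol = length(eps))
  loec <- matrix(NA_real_, nrow = length(usamp), ncol = length(eps))
  for (si in seq_along(usamp)) {
    i <- idx_by_sample[[si]]
    exceeds <- vals[i, , drop = FALSE] > rep(coff, each = length(i))
    any_hit <- colSums(exceeds) > 0L
    hit[si, any_hit] <- 1L
    if (any(any_hit)) {
      cc <- concs[i]
      loec[si, any_hit] <- apply(exceeds[, any_hit, drop = FALSE], 2L,
                                 function(e) min(cc[e]))
    }
  }
  res$hitc <- as.integer(t(hit))
  res$loec_uM <- as.numeric(t(loec))
  rep_of <- attr(pm, "replicate_of")
  res$chemical_id <- unname(rep_of[res$sample_id])
  res[, c("sample_id", "chemical_id", "endpoint_id",
          "bmad", "coff", "hitc", "loec_uM")]
}

#' Qualitative concordance of duplicate hit-call vectors
#'
#' Percent of endpoints on which two blinded duplicate samples agree in
#' their binary hit call.
#'
#' @param hitsA,hitsB named integer vectors of hit calls (names are
#'   endpoint ids) for the two duplicate samples of one chemical.
#' @return percent agreement in \[0, 100\].
#' @export
replicate_concordance <- function(hitsA, hitsB) {
  if (!setequal(names(hitsA), names(hitsB)) ||
      length(hitsA) != length(hitsB)) {
    stop("duplicate samples cover different endpoint sets")
  }
  hitsB <- hitsB[names(hitsA)]
  100 * mean(hitsA == hitsB)
}

#' Per-chemical replicate concordance summary
#'
#' For every chemical with exactly two samples, computes the percent of
#' endpoints with equal hit calls, and summarizes mean and sd across
#' chemicals.
#'
#' @param hits a hit-call table from [hitcall_table()].
#' @return list with `per_chemical` (data.frame `chemical_id`,
#'   `concordance_pct`) and `mean`, `sd` across chemicals.
#' @export
concordance_summary <- function(hits) {
  out <- lapply(split(hits, hits$chemical_id), function(h) {
    samp <- unique(h$sample_id)
    if (length(samp) != 2L) return(NULL)
    a <- h[h$sample_id == samp[1L], ]
    b <- h[h$sample_id == samp[2L], ]
    replicate_concordance(stats::setNames(a$hitc, a$endpoint_id),
                          stats::setNames(b$hitc, b$endpoint_id))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  per_chem <- data.frame(chemical_id = names(out),
                         concordance_pct = unlist(out, use.names = FALSE),
                         stringsAsFactors = FALSE)
  list(per_chemical = per_chem,
       mean = mean(per_chem$concordance_pct),
       sd = stats::sd(per_chem$concordance_pct))
}

#' Chemical-level activity: active in either duplicate sample
#'
#' @param hits a hit-call table from [hitcall_table()].
#' @return data.frame `chemical_id`, `endpoint_id`, `hitc` (0/1),
#'   `loec_uM` (minimum over active samples).
#' @export
chemical_hits <- function(hits) {
  key <- paste(hits$chemical_id, hits$endpoint_id, sep = "\r")
  hitc <- tapply(hits$hitc, key, max)
  loec <- tapply(hits$loec_uM, key, function(l) {
    l <- l[!is.na(l)]
    if (length(l) == 0L) NA_real_ else min(l)
  })
  parts <- do.call(rbind, strsplit(names(hitc), "\r", fixed = TRUE))
  data.frame(chemical_id = parts[, 1L], endpoint_id = parts[, 2L],
             hitc = as.integer(hitc), loec_uM = as.numeric(loec),
             row.names = NULL, stringsAsFactors = FALSE)
}
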