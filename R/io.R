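#' Read and write well-level screening tables
#'
#' The interchange format is a long CSV with one row per well and columns
#' `plate_id`, `well_id`, `sample_id`, `chemical_id`, `concentration_uM`,
#' `endpoint_id`, `raw_value`, `well_role`. Raw values are strictly
#' positive assay units; `well_role` is one of `treatment`,
#' `vehicle_control`, `positive_control`, `non_stim_control`. Reading
#' validates every record: unknown endpoints are rejected, raw values must
#' be positive, and each (plate, endpoint) must carry exactly 8 vehicle
#' wells.
#'
#' @param path file path.
#' @param vocabulary an [endpoint_vocabulary()] the records must resolve in.
#' @return `read_well_table()` returns a validated `data.frame` of wells.
#' @export
read_well_table <- function(path, vocabulary) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(concentration_uM = "numeric",
                                          raw_value = "numeric"))
  validate_well_table(wells, vocabulary)
}

#' @rdname read_well_table
#' @param wells a well table.
#' @export
write_well_table <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

WELL_COLUMNS <- c("plate_id", "well_id", "sample_id", "chemical_id",
                  "concentration_uM", "endpoint_id", "raw_value", "well_role")
WELL_ROLES <- c("treatment", "vehicle_control", "positive_control",
                "non_stim_control")

#' @rdname read_well_table
#' @export
validate_well_table <- function(wells, vocabulary) {
  missing_cols <- setdiff(WELL_COLUMNS, names(wells))
  if (length(missing_cols) > 0L) {
    stop("well table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  bad_raw <- which(!is.finite(wells$raw_value) | wells$raw_value <= 0)
  if (length(bad_raw) > 0L) {
    stop("validation error: raw_value must be > 0 (first offending row: ",
         bad_raw[1L], ")")
  }
  unknown <- setdiff(unique(wells$endpoint_id), vocabulary$endpoint_id)
  if (length(unknown) > 0L) {
    stop("validation error: unknown endpoint_id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  bad_role <- setdiff(unique(wells$well_role), WELL_ROLES)
  if (length(bad_role) > 0L) {
    stop("validation error: unknown well_role(s): ",
         paste(bad_role, collapse = ", "))
  }
  trt <- wells$well_role == "treatment"
  if (any(trt & wells$concentration_uM <= 0)) {
    stop("validation error: treatment wells require concentration_uM > 0")
  }
  veh <- wells[wells$well_role == "vehicle_control", c("plate_id", "endpoint_id")]
  n_veh <- table(paste(veh$plate_id, veh$endpoint_id, sep = "\r"))
  plates_seen <- unique(wells[trt, c("plate_id", "endpoint_id")])
  keys <- paste(plates_seen$plate_id, plates_seen$endpoint_id, sep = "\r")
  counts <- as.integer(n_veh[keys])
  counts[is.na(counts)] <- 0L
  off <- counts != 8L
  if (any(off)) {
    stop("validation error: plate ", plates_seen$plate_id[off][1L],
         " endpoint ", plates_seen$endpoint_id[off][1L], " has ",
         counts[off][1L], " vehicle wells (expected 8)")
  }
  wells
}

#' Level-5-style hit-call table I/O
#'
#' One row per sample-endpoint pair with columns `sample_id`,
#' `chemical_id`, `endpoint_id`, `bmad`, `coff`, `hitc`, `loec_uM`
#' (empty when `hitc = 0`).
#'
#' @param hits a hit-call table from [hitcall_table()].
#' @param path file path.
#' @export
write_level5_table <- function(hits, path) {
  out <- hits[, c("sample_id", "chemical_id", "endpoint_id",
                  "bmad", "coff", "hitc", "loec_uM")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_level5_table
#' @export
read_level5_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(bmad = "numeric", coff = "numeric",
                                 hitc = "integer", loec_uM = "numeric"))
}

#' Profile-matrix TSV I/O
#'
#' Rows are keyed `sample_id:concentration`; columns are endpoint ids. The
#' sample-to-chemical map is carried in a `chemical_id` column so the file
#' round-trips a [profile_matrix()] exactly.
#'
#' @param pm a [profile_matrix()].
#' @param path file path.
#' @export
write_profile_matrix <- function(pm, path) {
  df <- data.frame(sample_id = pm_samples(pm),
                   concentration_uM = pm_concs(pm),
                   chemical_id = pm_chemicals(pm),
                   unclass(pm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("sample_id", "concentration_uM", "chemical_id")
  values <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rep_of <- tapply(df$chemical_id, df$sample_id, `[`, 1L)
  profile_matrix(values, df$sample_id, df$concentration_uM,
                 stats::setNames(as.character(rep_of), names(rep_of)))
}

#' Envelope TSV I/O
#' @param envelope an envelope table from [build_envelope()].
#' @param path file path.
#' @export
write_envelope <- function(envelope, path) {
  utils::write.table(envelope, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Endpoint vocabulary CSV I/O (roles semicolon-joined)
#' @param vocabulary an [endpoint_vocabulary()].
#' @param path file path.
#' @export
write_endpoint_vocabulary <- function(vocabulary, path) {
  utils::write.csv(as.data.frame(vocabulary)[, c("endpoint_id", "system",
                                                 "biomarker", "is_down", "roles")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_endpoint_vocabulary
#' @export
read_endpoint_vocabulary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  endpoint_vocabulary(df$system, df$biomarker, df$is_down, df$roles)
}
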