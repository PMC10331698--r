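#' Run the full profiling pipeline
#'
#' Chains every stage in order: vehicle normalization, down-endpoint
#' inversion, historical envelope, hit calling, cytotoxicity flagging and
#' filtering, the nine-signature engine, similarity search (when a
#' reference database is supplied), two-pass SOM clustering, and plate QC.
#' With `out_dir` set, each stage's table is written there as CSV/TSV.
#'
#' @param config a [pipeline_config()].
#' @param wells a validated well table.
#' @param historical historical vehicle-control collection (see
#'   [generate_historical_controls()] / [build_envelope()]).
#' @param reference_db optional [reference_db()] for similarity search.
#' @param vocabulary an [endpoint_vocabulary()].
#' @param out_dir optional output directory.
#' @return list with every stage output: `profiles`, `profiles_inverted`,
#'   `envelope`, `hits`, `concordance`, `cytotox_counts`, `overt`,
#'   `cytotox_summary`, `signature_calls`, `signature_summaries`,
#'   `signature_table`, `similarity`, `som`, `qc_plates`.
#' @export
run_pipeline <- function(config, wells, historical, reference_db = NULL,
                         vocabulary = default_endpoints(), out_dir = NULL) {
  if (is.null(historical)) {
    stop("envelope stage requires historical controls; none supplied")
  }
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  wells <- stage("validate", validate_well_table(wells, vocabulary))
  pm <- stage("normalize", compute_log10_ratios(wells, vocabulary))
  pm_inv <- stage("normalize", invert_down_endpoints(pm, vocabulary))
  envelope <- stage("envelope", build_envelope(
    historical, coverage = config$envelope_coverage,
    method = config$envelope_method))

  hits <- stage("hitcall", hitcall_table(pm_inv, config))
  conc_summary <- stage("hitcall", concordance_summary(hits))

  counts <- stage("cytotox", cytotox_counts(pm, hits, vocabulary))
  overt <- stage("cytotox", flag_overt(pm, vocabulary,
                                       config$cytotox_log10ratio,
                                       strict = config$overt_strict))
  ct_summary <- stage("cytotox", cytotox_summary(pm, hits, vocabulary, config))

  sig_calls <- stage("signatures",
                     evaluate_signatures(pm, envelope, vocabulary, config))
  sig_summ <- stage("signatures",
                    summarize_signatures(sig_calls, attr(pm, "replicate_of")))
  sig_tab <- stage("signatures", signature_table(sig_summ))

  pm_filtered <- stage("cytotox", filter_for_profiling(
    pm, counts, config$max_cytotox_endpoints_for_profiling))
  sim <- if (!is.null(reference_db)) {
    stage("similarity", similarity_table(pm_filtered, reference_db, config))
  } else NULL

  som <- stage("cluster", two_pass_clustering(pm, counts, config))
  qc_plates <- stage("qc", plate_cv_table(wells))

  out <- list(profiles = pm, profiles_inverted = pm_inv, envelope = envelope,
              hits = hits, concordance = conc_summary,
              cytotox_counts = counts, overt = overt,
              cytotox_summary = ct_summary,
              signature_calls = sig_calls, signature_summaries = sig_summ,
              signature_table = sig_tab, similarity = sim, som = som,
              qc_plates = qc_plates, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_profile_matrix(out$profiles, p("profiles.tsv"))
  write_profile_matrix(out$profiles_inverted, p("profiles_inverted.tsv"))
  write_envelope(out$envelope, p("envelope.tsv"))
  write_level5_table(out$hits, p("hitcalls.csv"))
  utils::write.csv(out$concordance$per_chemical, p("concordance.csv"),
                   row.names = FALSE)
  utils::write.csv(out$cytotox_summary, p("cytotox_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(out$signature_calls, p("signature_calls.csv"),
                   row.names = FALSE)
  write_signature_table(out$signature_table, p("signature_table.csv"))
  if (!is.null(out$similarity)) {
    utils::write.csv(out$similarity, p("similarity.csv"), row.names = FALSE)
  }
  utils::write.csv(out$som$full$assignments, p("som_full_assignments.csv"),
                   row.names = FALSE)
  utils::write.csv(out$som$filtered$assignments,
                   p("som_filtered_assignments.csv"), row.names = FALSE)
  utils::write.table(out$som$filtered$model$codebook, p("som_codebook.tsv"),
                     sep = "\t", row.names = FALSE)
  utils::write.csv(out$qc_plates, p("qc_plates.csv"), row.names = FALSE)
  invisible(out_dir)
}
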