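#' Write a cohort bundle to plain-text files
#'
#' Writes the cohort values as CSV, the feature metadata plus configuration
#' echo as a JSON sidecar, and the municipality table (with its pollution
#' series, one column per year) as CSV.
#'
#' @param cohort a cohort bundle.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vals <- cbind(individual_id = seq_len(nrow(cohort$values)),
                municipality_id = cohort$municipality_id,
                cohort$values, cohort$labels)
  utils::write.csv(vals, file.path(dir, "cohort.csv"), row.names = FALSE)
  sidecar <- list(
    metadata = cohort$metadata,
    seed = cohort$config$seed,
    n_individuals = nrow(cohort$values),
    labels = colnames(cohort$labels))
  jsonlite::write_json(sidecar, file.path(dir, "cohort_metadata.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  muni <- cohort$municipalities
  tab <- muni$table
  for (m in muni$metrics) {
    series <- muni$pollution[[m]]
    colnames(series) <- sprintf("%s_year%02d", m, seq_len(ncol(series)))
    tab <- cbind(tab, series)
  }
  utils::write.csv(tab, file.path(dir, "municipalities.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write quasi-constancy diagnostics as CSV
#'
#' @param results the `results` data frame from [filter_quasi_constant()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_quasi_constancy <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' Serialize permutation-importance and selection results to JSON
#'
#' Exports the per-feature importance summary (and, when present, the
#' backward-selection trace) in a plotting-friendly layout: box-plot
#' quantiles of the per-repetition drops plus the CI of the mean.
#'
#' @param pi_results a [permutation_importance()] result.
#' @param sfs optional [backward_sfs()] trace.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(pi_results, path, sfs = NULL) {
  qs <- t(apply(pi_results$drops, 2, stats::quantile,
                probs = c(0.05, 0.25, 0.5, 0.75, 0.95)))
  colnames(qs) <- c("q05", "q25", "q50", "q75", "q95")
  out <- list(importance = cbind(pi_results$summary, as.data.frame(qs)))
  if (!is.null(sfs))
    out$sfs <- list(trace = sfs$trace, selected = sfs$selected,
                    best_score = sfs$best_score)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a model evaluation report as JSON plus ROC curve CSV
#'
#' @param evaluation a [crossval_evaluate()] result.
#' @param json_path output JSON file (per-fold AUROC, mean with CI,
#'   Youden-threshold metric means and SDs).
#' @param roc_csv_path optional CSV for the averaged ROC curve.
#' @return `json_path`, invisibly.
#' @export
write_evaluation_report <- function(evaluation, json_path,
                                    roc_csv_path = NULL) {
  out <- list(
    k = evaluation$k,
    fold_auroc = evaluation$fold_auroc,
    mean_auroc = evaluation$mean_auroc,
    ci = evaluation$ci,
    youden_mean = as.list(evaluation$youden_mean),
    youden_sd = as.list(evaluation$youden_sd))
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(roc_csv_path))
    utils::write.csv(evaluation$roc, roc_csv_path, row.names = FALSE)
  invisible(json_path)
}
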