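#' Empirical ROC curve points
#'
#' One row per distinct threshold (plus the flag-none endpoint), with the
#' true- and false-positive rates of predicting positive at or above it.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels.
#' @return Data frame with columns `threshold`, `tpr`, `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  th <- c(sort(unique(scores)), Inf)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  data.frame(threshold = th,
             tpr = vapply(th, function(t) sum(scores >= t & labels == 1) / n1, 0),
             fpr = vapply(th, function(t) sum(scores >= t & labels == 0) / n0, 0))
}

report_scalars <- function(report) {
  list(model_id = report$model_id, level = report$level,
       dag_source = report$dag_source,
       discretization = report$discretization,
       n = report$n, n_pos = report$n_pos,
       auc = report$roc$auc, auc_ci_low = report$roc$ci_low,
       auc_ci_high = report$roc$ci_high,
       tpr_05 = report$tpr_05, tnr_05 = report$tnr_05,
       tpr_05_ci = report$tpr_05_ci, tnr_05_ci = report$tnr_05_ci,
       tpr_at_tnr95 = report$tpr_at_tnr95,
       tpr_at_tnr95_ci = report$tpr_at_tnr95_ci,
       threshold_at_tnr95 = report$threshold_at_tnr95)
}

#' Write / read a model evaluation report
#'
#' `write_report` emits `<base>.json` with every report field (metadata,
#' ROC summary, calibration bins, stage histogram, net-benefit curve,
#' pooled out-of-fold scores) plus tidy CSV companions for the curves:
#' `<base>_roc.csv`, `<base>_calibration.csv`, `<base>_net_benefit.csv`.
#' `read_report` reconstructs the report from the JSON so that a write /
#' read round-trip is lossless (fold structures are written separately by
#' [run_grid()] and are not part of the JSON document).
#'
#' @param report A `"model_report"` from [evaluate_model()].
#' @param base Output path without extension.
#' @return `write_report` returns `base` invisibly; `read_report` a
#'   `"model_report"`.
#' @export
write_report <- function(report, base) {
  doc <- report_scalars(report)
  doc$calibration <- report$calibration
  doc$stage_histogram <- list(stages = rownames(report$stage_histogram),
                              bins = colnames(report$stage_histogram),
                              counts = unname(report$stage_histogram))
  doc$net_benefit <- report$net_benefit
  doc$scores <- report$scores
  doc$labels <- report$labels
  jsonlite::write_json(doc, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", na = "null",
                       matrix = "rowmajor")
  write.csv(roc_curve(report$scores, report$labels),
            paste0(base, "_roc.csv"), row.names = FALSE)
  write.csv(report$calibration, paste0(base, "_calibration.csv"),
            row.names = FALSE)
  write.csv(report$net_benefit, paste0(base, "_net_benefit.csv"),
            row.names = FALSE)
  invisible(base)
}

#' @rdname write_report
#' @export
read_report <- function(base) {
  doc <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  sh <- doc$stage_histogram
  hist <- matrix(as.integer(sh$counts), nrow = length(sh$stages), byrow = FALSE,
                 dimnames = list(sh$stages, sh$bins))
  rep <- list(model_id = doc$model_id, level = doc$level,
              dag_source = doc$dag_source,
              discretization = doc$discretization,
              n = doc$n, n_pos = doc$n_pos,
              roc = auc_ci(doc$auc, doc$n_pos, doc$n - doc$n_pos),
              tpr_05 = doc$tpr_05, tnr_05 = doc$tnr_05,
              tpr_05_ci = doc$tpr_05_ci, tnr_05_ci = doc$tnr_05_ci,
              tpr_at_tnr95 = doc$tpr_at_tnr95,
              tpr_at_tnr95_ci = doc$tpr_at_tnr95_ci,
              threshold_at_tnr95 = doc$threshold_at_tnr95,
              calibration = as.data.frame(doc$calibration),
              stage_histogram = hist,
              net_benefit = as.data.frame(doc$net_benefit),
              scores = doc$scores, labels = doc$labels,
              fold_dags = NULL)
  class(rep) <- "model_report"
  rep
}

#' Summarize a list of model reports as one table
#'
#' One row per model, shaped like a grid-results table (model number by
#' metric).
#'
#' @param reports List of `"model_report"` objects.
#' @return Data frame.
#' @export
summarize_reports <- function(reports) {
  rows <- lapply(reports, function(r) {
    data.frame(model_id = r$model_id, level = r$level,
               dag_source = r$dag_source, discretization = r$discretization,
               auc = r$roc$auc, auc_ci_low = r$roc$ci_low,
               auc_ci_high = r$roc$ci_high,
               tnr_05 = r$tnr_05, tpr_05 = r$tpr_05,
               tpr_at_tnr95 = r$tpr_at_tnr95,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
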