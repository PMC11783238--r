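#' Stratified cross-validation folds
#'
#' Class-wise round-robin assignment after a seeded shuffle, so per-fold
#' positive counts differ by at most one.
#'
#' @param labels Binary vector (0/1 or logical).
#' @param k Fold count.
#' @param seed Integer seed.
#' @return A `"fold_assignment"` list with `k`, `assignment` (fold index
#'   per record) and `seed`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  labels <- as.integer(labels)
  if (min(table(labels)) < k)
    stop_("each class must have at least k records")
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = k, assignment = assignment, seed = seed),
            class = "fold_assignment")
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic: the probability that a random positive scores
#' above a random negative, counting ties as one half.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_("both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Closed-form variance
#' `[A(1-A) + (n1-1)(q1-A^2) + (n0-1)(q2-A^2)] / (n1*n0)` with
#' `q1 = A/(2-A)`, `q2 = 2A^2/(1+A)`; the 95% interval is
#' `A +/- 1.96 sqrt(var)`, clipped to `[0, 1]`.
#'
#' @param auc Point estimate.
#' @param n_pos,n_neg Class sizes (each at least 2).
#' @param level Confidence level.
#' @return A `"roc_summary"` list with `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `q1`, `q2`, `var`.
#' @export
auc_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  if (n_pos < 2 || n_neg < 2) stop_("need at least two records per class")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
        (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(auc = auc,
                 ci_low = max(0, auc - z * sqrt(v)),
                 ci_high = min(1, auc + z * sqrt(v)),
                 n_pos = n_pos, n_neg = n_neg, q1 = q1, q2 = q2, var = v),
            class = "roc_summary")
}

#' Sensitivity and specificity at a probability cutoff
#'
#' Predicted positive iff `score >= cutoff`.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels.
#' @param cutoff Decision threshold (default 0.5).
#' @return List with `tpr` and `tnr`.
#' @export
rates_at_cutoff <- function(scores, labels, cutoff = 0.5) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0)) stop_("both classes required")
  pred <- scores >= cutoff
  list(tpr = mean(pred[labels == 1]), tnr = mean(!pred[labels == 0]))
}

#' Sensitivity at a fixed specificity
#'
#' The threshold is the smallest observed score `t` such that the fraction
#' of negatives scoring below `t` reaches `tnr_target` (empirical
#' quantile, no interpolation); the TPR is the fraction of positives at or
#' above `t`. When no observed score reaches the target the TPR is 0 with
#' a sentinel threshold above the maximum score.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels.
#' @param tnr_target Required specificity (default 0.95).
#' @return List with `tpr` and `threshold`.
#' @export
tpr_at_tnr <- function(scores, labels, tnr_target = 0.95) {
  labels <- as.integer(labels)
  neg <- scores[labels == 0]
  pos <- scores[labels == 1]
  if (!length(neg) || !length(pos)) stop_("both classes required")
  if (tnr_target <= 0) return(list(tpr = 1, threshold = -Inf))
  cand <- sort(unique(scores))
  tnr <- vapply(cand, function(t) mean(neg < t), 0)
  hit <- which(tnr >= tnr_target)
  if (!length(hit)) {
    sentinel <- max(scores) + 1
    return(list(tpr = 0, threshold = sentinel))
  }
  t <- cand[hit[1]]
  list(tpr = mean(pos >= t), threshold = t)
}

#' Wilson score interval for a binomial rate
#'
#' @param x Successes.
#' @param n Trials.
#' @param level Confidence level.
#' @return c(low, high).
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Calibration bins of predicted risk
#'
#' Ten half-open bins of width 0.1 (the last closed at 1.0), each with the
#' record count, mean predicted risk and observed event rate. Empty bins
#' are reported with `n = 0`.
#'
#' @param scores Predicted risks in `[0, 1]`.
#' @param labels Binary labels.
#' @param width Bin width.
#' @return Data frame with columns `lower`, `upper`, `n`, `mean_predicted`,
#'   `observed_rate`.
#' @export
calibration_bins <- function(scores, labels, width = 0.1) {
  labels <- as.integer(labels)
  nb <- round(1 / width)
  idx <- pmin(floor(scores / width) + 1L, nb)  # score 1.0 -> last bin
  out <- data.frame(lower = (seq_len(nb) - 1) * width,
                    upper = seq_len(nb) * width)
  out$n <- vapply(seq_len(nb), function(b) sum(idx == b), 0L)
  out$mean_predicted <- vapply(seq_len(nb), function(b)
    if (any(idx == b)) mean(scores[idx == b]) else NA_real_, 0)
  out$observed_rate <- vapply(seq_len(nb), function(b)
    if (any(idx == b)) mean(labels[idx == b]) else NA_real_, 0)
  out
}

#' Stage-stratified histogram of predicted risk
#'
#' Counts of positive (staged) records per (stage, risk bin) cell,
#' mirroring a stage-stratified calibration plot.
#'
#' @param scores Predicted risks of the positive records.
#' @param stages Stage per record (`I`..`IV`, `unknown`).
#' @param width Risk-bin width.
#' @return Matrix stages x bins of counts.
#' @export
stage_calibration <- function(scores, stages, width = 0.1) {
  nb <- round(1 / width)
  idx <- pmin(floor(scores / width) + 1L, nb)
  lv <- intersect(c("I", "II", "III", "IV", "unknown"), unique(stages))
  out <- matrix(0L, nrow = length(lv), ncol = nb,
                dimnames = list(lv, sprintf("[%.1f,%.1f)",
                                            (seq_len(nb) - 1) * width,
                                            seq_len(nb) * width)))
  for (s in lv) out[s, ] <- tabulate(idx[stages == s], nbins = nb)
  out
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at threshold probability `p_t`:
#' `NB_model = TP/n - (FP/n) * p_t / (1 - p_t)`, compared with flagging
#' every patient (`NB_all = pi - (1 - pi) * p_t / (1 - p_t)`, `pi` the
#' prevalence) and flagging none (`NB_none = 0`).
#'
#' @param scores Predicted risks.
#' @param labels Binary labels.
#' @param thresholds Threshold grid in `(0, 1)`.
#' @return Data frame with columns `threshold`, `tp`, `fp`,
#'   `net_benefit_model`, `net_benefit_all`, `net_benefit_none`.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds >= 1)) stop_("thresholds must be below 1")
  labels <- as.integer(labels)
  n <- length(labels)
  pi0 <- mean(labels)
  rows <- lapply(thresholds, function(pt) {
    pred <- scores >= pt
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    w <- pt / (1 - pt)
    data.frame(threshold = pt, tp = tp, fp = fp,
               net_benefit_model = tp / n - fp / n * w,
               net_benefit_all = pi0 - (1 - pi0) * w,
               net_benefit_none = 0)
  })
  do.call(rbind, rows)
}

#' Cross-validated evaluation of one model configuration
#'
#' Runs the full per-fold pipeline for one cell of the experimental grid:
#' the discretization scheme is learned on the training fold only, applied
#' to all records, the injected-missingness mask (if any) is then imposed,
#' the structure is taken from the expert DAG or learned by K2 on the
#' imputed training fold, parameters are fitted by EM on the incomplete
#' training fold, and out-of-fold risks are pooled across folds before any
#' metric is computed.
#'
#' @param cohort A continuous [bn_cohort()] (with baseline missingness).
#' @param folds A [stratified_folds()] assignment over the cohort.
#' @param dag_source `"learned"` or `"expert"`.
#' @param discretization `"clinical"` or `"mdl"`.
#' @param expert_dag A `"bn_dag"` (required when `dag_source = "expert"`).
#' @param mask Optional deletion log (data frame `record_id`, `column`)
#'   from [inject_mcar()] applied after discretization.
#' @param k2 A [k2_config()] for learned structures.
#' @param em An [em_config()].
#' @param model_id,level Metadata copied into the report.
#' @return A `"model_report"`: metadata, `roc` ([auc_ci()] summary),
#'   `tpr_05`, `tnr_05`, `tpr_at_tnr95` (+ Wilson CI and threshold),
#'   `calibration`, `stage_histogram`, `net_benefit`, `scores`, plus the
#'   learned structures per fold.
#' @export
evaluate_model <- function(cohort, folds,
                           dag_source = c("learned", "expert"),
                           discretization = c("clinical", "mdl"),
                           expert_dag = NULL, mask = NULL,
                           k2 = k2_config(), em = em_config(),
                           model_id = NA, level = 0) {
  dag_source <- match.arg(dag_source)
  discretization <- match.arg(discretization)
  if (dag_source == "expert" && is.null(expert_dag))
    stop_("expert DAG required")
  reg <- cohort$registry
  out_var <- outcome_var(reg)
  pos <- reg[[out_var]]$states[2]
  labels <- as.integer(cohort$data[[out_var]] == pos)
  n <- n_records(cohort)
  scores <- rep(NA_real_, n)
  fold_dags <- list()

  for (f in seq_len(folds$k)) {
    tr <- folds$assignment != f
    train_cont <- subset_cohort(cohort, tr)
    scheme <- if (discretization == "clinical") clinical_scheme(reg)
              else learn_mdl_scheme(mask_cohort(train_cont, mask))
    disc <- discretize_cohort(cohort, scheme)
    disc <- mask_cohort(disc, mask)
    train <- subset_cohort(disc, tr)
    test <- subset_cohort(disc, !tr)
    dag <- if (dag_source == "expert") expert_dag
           else k2_search(mean_mode_impute(train), k2)
    fit <- em_fit(dag, train, em)
    scores[!tr] <- predict_cohort(fit$bn, test)
    fold_dags[[f]] <- dag
  }

  roc <- auc_ci(roc_auc(scores, labels), sum(labels == 1), sum(labels == 0))
  r05 <- rates_at_cutoff(scores, labels, 0.5)
  t95 <- tpr_at_tnr(scores, labels, 0.95)
  n_pos <- sum(labels == 1)
  stages <- cohort$data$stage[labels == 1]
  rep <- list(model_id = model_id, level = level,
              dag_source = dag_source, discretization = discretization,
              n = n, n_pos = n_pos,
              roc = roc,
              tpr_05 = r05$tpr, tnr_05 = r05$tnr,
              tpr_05_ci = wilson_interval(round(r05$tpr * n_pos), n_pos),
              tnr_05_ci = wilson_interval(round(r05$tnr * (n - n_pos)), n - n_pos),
              tpr_at_tnr95 = t95$tpr,
              tpr_at_tnr95_ci = wilson_interval(round(t95$tpr * n_pos), n_pos),
              threshold_at_tnr95 = t95$threshold,
              calibration = calibration_bins(scores, labels),
              stage_histogram = stage_calibration(scores[labels == 1], stages),
              net_benefit = decision_curve(scores, labels),
              scores = scores, labels = labels,
              fold_dags = fold_dags)
  class(rep) <- "model_report"
  rep
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> model %s | missing %.0f%% | %s DAG | %s discretization\n",
              x$model_id, 100 * x$level, x$dag_source, x$discretization))
  cat(sprintf("  AUC %.3f (%.3f-%.3f), TPR@0.5 %.3f, TNR@0.5 %.3f, TPR@TNR95 %.3f\n",
              x$roc$auc, x$roc$ci_low, x$roc$ci_high,
              x$tpr_05, x$tnr_05, x$tpr_at_tnr95))
  invisible(x)
}

# Apply a deletion log (record_id, column) to a cohort.
mask_cohort <- function(cohort, mask) {
  if (is.null(mask) || !nrow(mask)) return(cohort)
  d <- cohort$data
  row_of <- match(mask$record_id, d$id)
  keep <- !is.na(row_of)
  for (cl in unique(mask$column[keep])) {
    rows <- row_of[keep][mask$column[keep] == cl]
    d[[cl]][rows] <- NA
  }
  out <- cohort
  out$data <- d
  out
}
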