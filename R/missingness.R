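#' Missingness-injection plan
#'
#' Describes a controlled missing-completely-at-random degradation of a
#' cohort: a fraction of the currently observed predictor cells is deleted
#' uniformly at random. The outcome and stage are always protected (they
#' define the evaluation), as is the record id.
#'
#' @param rate Fraction of observed unprotected cells to delete (the study
#'   levels are 0, 0.10, 0.20, 0.30, but any value in `[0, 1]` works).
#' @param protected Additional protected column names.
#' @param seed Integer seed making the deletion reproducible.
#' @return A `"missingness_plan"`.
#' @export
missingness_plan <- function(rate, protected = character(0), seed = 1) {
  if (rate < 0 || rate > 1) stop_("rate must be in [0, 1]")
  structure(list(rate = rate, protected = protected, seed = seed),
            class = "missingness_plan")
}

#' Inject missing-completely-at-random cells
#'
#' Deletes exactly `round(rate * |E|)` cells, where `E` is the set of
#' observed cells in unprotected predictor columns, drawn uniformly
#' without replacement. The input cohort is not modified; the deletion log
#' lists each removed `(record id, column)` pair. Deletion is independent
#' of all values (including the outcome), so the mechanism is MCAR by
#' construction, and the same seed reproduces the same log bit for bit.
#'
#' @param cohort A [bn_cohort()] (continuous or discretized).
#' @param plan A [missingness_plan()].
#' @return List with `cohort` (degraded copy) and `log` (data frame with
#'   columns `record_id`, `column`).
#' @export
inject_mcar <- function(cohort, plan) {
  reg <- cohort$registry
  out_var <- outcome_var(reg)
  columns <- setdiff(registry_names(reg), c(out_var, plan$protected))
  d <- cohort$data
  obs <- which(!is.na(as.matrix(d[, columns, drop = FALSE])), arr.ind = TRUE)
  n_del <- round(plan$rate * nrow(obs))
  if (n_del > 0) {
    pick <- with_seed(plan$seed, sample.int(nrow(obs), n_del))
    pick <- sort(pick)
    for (ci in unique(obs[pick, 2])) {
      rows <- obs[pick, 1][obs[pick, 2] == ci]
      d[[columns[ci]]][rows] <- NA
    }
    log <- data.frame(record_id = d$id[obs[pick, 1]],
                      column = columns[obs[pick, 2]],
                      stringsAsFactors = FALSE)
  } else {
    log <- data.frame(record_id = character(0), column = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- cohort
  out$data <- d
  list(cohort = out, log = log)
}
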