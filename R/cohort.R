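#' Patient cohort container
#'
#' A cohort bundles a variable registry with a data frame of patient
#' records. The data frame holds one row per patient with columns `id`,
#' `stage`, the outcome column (named after the registry's outcome
#' variable) and one column per predictor. Missing values are `NA`.
#'
#' @param registry A [bn_registry()].
#' @param data Data frame of records.
#' @param validate Check invariants (unique ids, known states, stage
#'   consistency)? Default `TRUE`.
#'
#' @return An object of class `"bn_cohort"`.
#' @export
bn_cohort <- function(registry, data, validate = TRUE) {
  out_var <- outcome_var(registry)
  need <- c("id", "stage", registry_names(registry))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_("cohort data lacks column(s): ", paste(miss, collapse = ", "))
  data <- data[, need, drop = FALSE]
  data$id <- as.character(data$id)
  data$stage <- as.character(data$stage)
  cohort <- structure(list(registry = registry, data = data),
                      class = "bn_cohort")
  if (validate) validate_cohort(cohort)
  cohort
}

n_records <- function(cohort) nrow(cohort$data)

valid_stages <- c("I", "II", "III", "IV", "unknown", "not-applicable")

validate_cohort <- function(cohort) {
  reg <- cohort$registry
  d <- cohort$data
  if (anyDuplicated(d$id)) stop_("duplicate record ids")
  bad_stage <- setdiff(unique(d$stage[!is.na(d$stage)]), valid_stages)
  if (length(bad_stage))
    stop_("invalid stage value(s): ", paste(bad_stage, collapse = ", "))
  out_var <- outcome_var(reg)
  pos <- reg[[out_var]]$states[2]
  if (any(!is.na(d$stage) & d$stage != "not-applicable" &
          (is.na(d[[out_var]]) | d[[out_var]] != pos)))
    stop_("stage other than 'not-applicable' on a non-", pos, " record")
  for (v in registry_names(reg)) {
    s <- reg[[v]]
    x <- d[[v]]
    if (s$kind == "continuous") {
      if (!is.numeric(x)) {
        # a discretized cohort carries character states instead
        states <- attr(cohort, "states")[[v]]
        if (is.null(states))
          stop_("column '", v, "' is not numeric and no discrete states are attached")
        bad <- setdiff(unique(x[!is.na(x)]), states)
        if (length(bad)) stop_("column '", v, "': unknown state(s) ",
                               paste(bad, collapse = ", "))
      }
    } else {
      bad <- setdiff(unique(x[!is.na(x)]), s$states)
      if (length(bad))
        stop_("column '", v, "': unknown state(s) ", paste(bad, collapse = ", "))
    }
  }
  invisible(cohort)
}

#' @export
print.bn_cohort <- function(x, ...) {
  out_var <- outcome_var(x$registry)
  pos <- x$registry[[out_var]]$states[2]
  npos <- sum(x$data[[out_var]] == pos, na.rm = TRUE)
  cat("<bn_cohort> ", n_records(x), " records, ", npos, " ", pos,
      " (", sprintf("%.1f%%", 100 * npos / max(1, n_records(x))), "), ",
      length(lab_vars(x$registry)), " labs",
      if (!is.null(attr(x, "states"))) ", discretized" else "", "\n", sep = "")
  invisible(x)
}

#' Read a patient cohort from CSV
#'
#' The CSV must have a header with columns `id`, `label`, `stage` and one
#' column per registry predictor. `label` holds the outcome states. Missing
#' cells are encoded as the empty string or the literal `NA`; anything else
#' that fails to parse for a continuous column is an error.
#'
#' @param path CSV file path.
#' @param registry A [bn_registry()]; defaults to the bundled lung-cancer
#'   registry.
#' @return A [bn_cohort()].
#' @export
read_cohort <- function(path, registry = default_lc_registry()) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = c("", "NA"))
  out_var <- outcome_var(registry)
  need <- c("id", "label", "stage", setdiff(registry_names(registry), out_var))
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_("cohort CSV lacks column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(id = raw$id, stage = raw$stage, stringsAsFactors = FALSE)
  d[[out_var]] <- raw$label
  for (v in setdiff(registry_names(registry), out_var)) {
    s <- registry[[v]]
    x <- raw[[v]]
    if (s$kind == "continuous") {
      num <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & is.na(num)
      if (any(bad))
        stop_("column '", v, "': unparseable value(s), e.g. '",
              x[which(bad)[1]], "'")
      d[[v]] <- num
    } else {
      d[[v]] <- x
    }
  }
  bn_cohort(registry, d)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, the
#' outcome column is written as `label`. Round-trips losslessly.
#'
#' @param cohort A [bn_cohort()].
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  reg <- cohort$registry
  out_var <- outcome_var(reg)
  d <- cohort$data
  out <- data.frame(id = d$id, label = d[[out_var]], stage = d$stage,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (v in setdiff(registry_names(reg), out_var)) out[[v]] <- d[[v]]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Laboratory-panel inclusion filter
#'
#' Retains patients with at least `min_labs` of the `total_labs` laboratory
#' analyses observed (the study design allows at most three missing labs
#' out of twenty). Record order is preserved; the filter is idempotent.
#'
#' @param cohort A [bn_cohort()].
#' @param min_labs Minimum observed labs to retain a record.
#' @param total_labs Expected size of the lab panel in the registry.
#' @return The filtered cohort.
#' @export
apply_inclusion_filter <- function(cohort, min_labs = 17, total_labs = 20) {
  labs <- lab_vars(cohort$registry)
  if (length(labs) != total_labs)
    stop_("registry has ", length(labs), " lab variables, expected ", total_labs)
  if (min_labs > total_labs) stop_("min_labs exceeds total_labs")
  n_obs <- rowSums(!is.na(cohort$data[, labs, drop = FALSE]))
  keep <- n_obs >= min_labs
  out <- cohort
  out$data <- cohort$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  tr <- attr(cohort, "truth")
  if (!is.null(tr)) attr(out, "truth") <- tr[keep, , drop = FALSE]
  out
}
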