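#' K2 search configuration
#'
#' @param ordering Node ordering (permutation of the model variables) or
#'   `NULL` for the default implied by `start`: outcome-first places the
#'   outcome node first and the remaining variables in registry order;
#'   unconstrained uses plain registry order.
#' @param max_parents Per-node parent cap, 0..10.
#' @param start `"outcome-first"` seeds an edge outcome -> node for every
#'   other node before the greedy search; `"unconstrained"` starts from an
#'   empty parent set.
#' @return A `"k2_config"`.
#' @export
k2_config <- function(ordering = NULL,
                      max_parents = 3,
                      start = c("outcome-first", "unconstrained")) {
  start <- match.arg(start)
  if (max_parents < 0 || max_parents > 10)
    stop_("max_parents must be in 0..10")
  structure(list(ordering = ordering, max_parents = as.integer(max_parents),
                 start = start), class = "k2_config")
}

#' EM configuration
#'
#' @param tol Relative observed-data log-likelihood change below which EM
#'   stops.
#' @param max_iter Iteration cap.
#' @param prior_alpha Dirichlet pseudo-count per CPT cell used in the
#'   M-step (and by [mle_fit()] for the initialization).
#' @param seed Reserved (initialization is deterministic).
#' @return An `"em_config"`.
#' @export
em_config <- function(tol = 1e-6, max_iter = 100, prior_alpha = 0.5,
                      seed = NULL) {
  stopifnot(tol > 0, max_iter >= 1, prior_alpha >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 prior_alpha = prior_alpha, seed = seed),
            class = "em_config")
}

# Discretized cohort -> list(nodes, cards, states, m0) with m0 a 0-based
# integer matrix in registry node order.
learn_data <- function(cohort) {
  states <- cohort_states(cohort)
  nodes <- registry_names(cohort$registry)
  m <- cohort_int_matrix(cohort, nodes, states)
  list(nodes = nodes, states = states,
       cards = vapply(states[nodes], length, 0L), m = m)
}

#' Sufficient counts of one CPT family
#'
#' Tabulates `N_jk`, the number of records with the node in state `k`
#' under parent configuration `j`, from complete data.
#'
#' @param cohort A complete discretized [bn_cohort()].
#' @param structure A `"bn_dag"`.
#' @param node Node name.
#' @return A `"sufficient_counts"` list with fields `node`, `parents`,
#'   `r`, `q`, `N_jk` (q x r matrix) and `N_j` (row sums).
#' @export
collect_counts <- function(cohort, structure, node) {
  ld <- learn_data(cohort)
  pa <- bn_parents(structure, node)
  fam <- c(pa, node)
  if (anyNA(ld$m[, fam]))
    stop_("missing value in family of '", node, "' (complete data required)")
  N <- cpp_counts(ld$m, ld$cards, match(node, ld$nodes) - 1L,
                  match(pa, ld$nodes) - 1L)
  res <- list(node = node, parents = pa, r = ncol(N), q = nrow(N),
              N_jk = N, N_j = rowSums(N))
  class(res) <- "sufficient_counts"
  res
}

#' Cooper-Herskovits family log-score
#'
#' The K2 marginal likelihood of one node given its parent set, in log
#' form: `sum_j [ lgamma(r) - lgamma(N_j + r) + sum_k lgamma(N_jk + 1) ]`.
#'
#' @param counts A `"sufficient_counts"` (or any list with `N_jk` and `r`).
#' @return Log score (0 for empty data).
#' @export
k2_family_logscore <- function(counts) {
  N <- counts$N_jk
  r <- ncol(N)
  sum(lgamma(r) - lgamma(rowSums(N) + r)) + sum(lgamma(N + 1))
}

# Internal score from the raw integer matrix (avoids rebuilding cohorts in
# the greedy loop).
family_logscore_m <- function(m, cards, node_i, parent_i) {
  N <- cpp_counts(m, cards, node_i - 1L, parent_i - 1L)
  r <- ncol(N)
  sum(lgamma(r) - lgamma(rowSums(N) + r)) + sum(lgamma(N + 1))
}

#' Mean / mode imputation
#'
#' Continuous missing values become the column mean, discrete ones the
#' most frequent state (ties broken by registry state order). This is the
#' complete-data surrogate used before structure learning; parameter
#' learning proper uses [em_fit()] on the incomplete data.
#'
#' @param cohort A [bn_cohort()] (continuous or discretized).
#' @return The cohort with all model variables complete.
#' @export
mean_mode_impute <- function(cohort) {
  reg <- cohort$registry
  d <- cohort$data
  disc_states <- attr(cohort, "states")
  for (v in registry_names(reg)) {
    x <- d[[v]]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop_("column '", v, "' is fully missing")
    if (is.numeric(x)) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    } else {
      states <- if (!is.null(disc_states)) disc_states[[v]] else reg[[v]]$states
      tab <- table(factor(x, levels = states))
      x[is.na(x)] <- states[which.max(tab)]  # which.max: first tie wins
    }
    d[[v]] <- x
  }
  out <- cohort
  out$data <- d
  out
}

#' K2 greedy structure search
#'
#' For each node in the ordering, greedily adds the predecessor parent
#' whose addition most improves the Cooper-Herskovits family score,
#' stopping when no candidate improves the score or the parent cap is
#' reached. With the outcome-first start, the outcome node heads the
#' ordering and an edge outcome -> node is seeded for every other node
#' before the search (when the cap allows any parents at all).
#'
#' @param cohort A complete discretized [bn_cohort()] (use
#'   [mean_mode_impute()] first if needed).
#' @param config A [k2_config()].
#' @return A `"bn_dag"` over the registry variables (registry order).
#' @export
k2_search <- function(cohort, config = k2_config()) {
  ld <- learn_data(cohort)
  if (anyNA(ld$m)) stop_("K2 requires complete data; impute first")
  out_var <- outcome_var(cohort$registry)
  ordering <- config$ordering %||% switch(
    config$start,
    "outcome-first" = c(out_var, setdiff(ld$nodes, out_var)),
    "unconstrained" = ld$nodes)
  if (!setequal(ordering, ld$nodes) || length(ordering) != length(ld$nodes))
    stop_("ordering must be a permutation of the model variables")
  if (config$start == "outcome-first" && ordering[1] != out_var)
    stop_("outcome-first start requires the outcome to head the ordering")

  edges <- NULL
  for (pos in seq_along(ordering)) {
    v <- ordering[pos]
    vi <- match(v, ld$nodes)
    preds <- ordering[seq_len(pos - 1)]
    parents <- character(0)
    if (config$start == "outcome-first" && v != out_var &&
        config$max_parents >= 1)
      parents <- out_var
    score <- family_logscore_m(ld$m, ld$cards, vi, match(parents, ld$nodes))
    while (length(parents) < config$max_parents) {
      cand <- setdiff(preds, parents)
      if (!length(cand)) break
      trial <- vapply(cand, function(p)
        family_logscore_m(ld$m, ld$cards, vi,
                          match(c(parents, p), ld$nodes)), 0)
      best <- which.max(trial)
      if (trial[best] <= score + 1e-9) break
      parents <- c(parents, cand[best])
      score <- trial[best]
    }
    if (length(parents))
      edges <- rbind(edges, cbind(parents, v))
  }
  new_dag(ld$nodes, edges)
}

#' Fit CPTs by smoothed maximum likelihood on complete data
#'
#' CPT rows are `(N_jk + alpha) / (N_j + r * alpha)`; with `alpha = 0` an
#' entirely unobserved parent configuration falls back to a uniform row so
#' the CPT stays valid.
#'
#' @param structure A `"bn_dag"`.
#' @param cohort A complete discretized [bn_cohort()].
#' @param prior_alpha Dirichlet pseudo-count per cell.
#' @return A [bayesian_network()].
#' @export
mle_fit <- function(structure, cohort, prior_alpha = 0.5) {
  ld <- learn_data(cohort)
  cpts <- list()
  for (v in ld$nodes) {
    pa <- bn_parents(structure, v)
    if (anyNA(ld$m[, c(pa, v)]))
      stop_("missing value in family of '", v, "' (complete data required)")
    N <- cpp_counts(ld$m, ld$cards, match(v, ld$nodes) - 1L,
                    match(pa, ld$nodes) - 1L)
    r <- ncol(N)
    denom <- rowSums(N) + r * prior_alpha
    M <- (N + prior_alpha) / denom
    M[denom == 0, ] <- 1 / r
    cpts[[v]] <- M
  }
  bayesian_network(structure, ld$states, cpts,
                   outcome = outcome_var(cohort$registry))
}

#' Fit CPTs by expectation-maximization under missing data
#'
#' Initializes from [mle_fit()] on the mean/mode-imputed cohort, then
#' alternates an exact E-step (expected family counts from the joint
#' posterior over each record's missing variables, computed by exact
#' inference) with a Dirichlet-smoothed M-step, until the relative change
#' in observed-data log-likelihood falls below `tol` or `max_iter` is
#' reached. Non-convergence is reported in the result, not raised.
#'
#' @param structure A `"bn_dag"`.
#' @param cohort A discretized [bn_cohort()], possibly incomplete.
#' @param config An [em_config()].
#' @return A list with `bn` (the fitted [bayesian_network()]), `trace`
#'   (observed-data log-likelihood per iteration, non-decreasing),
#'   `converged` and `iterations`.
#' @export
em_fit <- function(structure, cohort, config = em_config()) {
  ld <- learn_data(cohort)
  init <- mle_fit(structure, mean_mode_impute(cohort), config$prior_alpha)
  fl <- bn_flat(init)
  res <- cpp_em(fl$cards, fl$parents0, fl$cpts, ld$m,
                config$prior_alpha, config$tol, config$max_iter)
  cpts <- list()
  for (i in seq_along(fl$nodes)) {
    v <- fl$nodes[i]
    r <- fl$cards[i]
    cpts[[v]] <- matrix(res$cpts[[i]], ncol = r, byrow = TRUE)
  }
  bn <- bayesian_network(structure, ld$states, cpts,
                         outcome = outcome_var(cohort$registry))
  list(bn = bn, trace = as.numeric(res$trace),
       converged = isTRUE(res$converged), iterations = res$iterations)
}

#' Observed-data log-likelihood
#'
#' Sum over records of `log P(observed cells)`, marginalizing missing
#' cells by exact inference. A fully missing record contributes 0.
#'
#' @param bn A [bayesian_network()].
#' @param cohort A discretized [bn_cohort()].
#' @return Scalar log-likelihood.
#' @export
observed_loglik <- function(bn, cohort) {
  fl <- bn_flat(bn)
  m <- cohort_int_matrix(cohort, fl$nodes, bn$states)
  ll <- cpp_loglik(fl$cards, fl$parents0, fl$cpts, m)
  if (any(!is.finite(ll)))
    stop_("record with zero probability under the model")
  sum(ll)
}

#' Select a K2 structure by cross-validated AUC
#'
#' Evaluates every combination of start mode and parent cap by pooled
#' out-of-fold AUC (structure re-learned per training fold on imputed
#' data, parameters by EM on the incomplete fold) and returns the winning
#' configuration's structure learned on the full imputed cohort, together
#' with the full selection table.
#'
#' @param cohort A discretized [bn_cohort()].
#' @param parent_limits Integer vector of parent caps to try.
#' @param starts Character vector of start modes.
#' @param cv_folds Folds for the internal cross-validation.
#' @param seed Seed for fold assignment.
#' @param em Parameter-learning configuration.
#' @return List with `structure` (a `"bn_dag"`), `best` (one-row data
#'   frame) and `table` (start x cap selection table with `cv_auc` and
#'   `n_edges`).
#' @export
select_structure <- function(cohort, parent_limits = 1:10,
                             starts = c("outcome-first", "unconstrained"),
                             cv_folds = 10, seed = 1,
                             em = em_config()) {
  out_var <- outcome_var(cohort$registry)
  pos <- cohort_states(cohort)[[out_var]][2]
  labels <- as.integer(cohort$data[[out_var]] == pos)
  folds <- stratified_folds(labels, k = cv_folds, seed = seed)
  rows <- list()
  for (start in starts) for (cap in parent_limits) {
    scores <- rep(NA_real_, n_records(cohort))
    cfg <- k2_config(max_parents = cap, start = start)
    for (f in seq_len(cv_folds)) {
      tr <- folds$assignment != f
      train <- subset_cohort(cohort, tr)
      test <- subset_cohort(cohort, !tr)
      dag <- k2_search(mean_mode_impute(train), cfg)
      fit <- em_fit(dag, train, em)
      scores[!tr] <- predict_cohort(fit$bn, test)
    }
    auc <- roc_auc(scores, labels)
    nedge <- nrow(k2_search(mean_mode_impute(cohort), cfg)$edges)
    rows[[length(rows) + 1]] <- data.frame(start = start, max_parents = cap,
                                           cv_auc = auc, n_edges = nedge)
  }
  tab <- do.call(rbind, rows)
  best <- tab[which.max(tab$cv_auc), , drop = FALSE]
  cfg <- k2_config(max_parents = best$max_parents, start = best$start)
  list(structure = k2_search(mean_mode_impute(cohort), cfg),
       best = best, table = tab)
}

# Row-subset a (possibly discretized) cohort, keeping attributes aligned.
subset_cohort <- function(cohort, keep) {
  out <- cohort
  out$data <- cohort$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  tr <- attr(cohort, "truth")
  if (!is.null(tr)) attr(out, "truth") <- tr[keep, , drop = FALSE]
  out
}
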