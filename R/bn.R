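#' Discrete Bayesian network
#'
#' Couples a DAG with one conditional probability table (CPT) per node. A
#' CPT is a `q x r` matrix: one row per configuration of the node's
#' parents (lexicographic over parent states in DAG node order, first
#' parent most significant) and one column per node state; every row sums
#' to one.
#'
#' @param dag A [new_dag()].
#' @param states Named list: ordered state labels per node.
#' @param cpts Named list of CPT matrices, one per node.
#' @param outcome Optional outcome node name used by [predict_risk()].
#' @return An object of class `"bayesian_network"`.
#' @export
bayesian_network <- function(dag, states, cpts, outcome = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  miss <- setdiff(dag$nodes, names(states))
  if (length(miss)) stop_("states missing for: ", paste(miss, collapse = ", "))
  miss <- setdiff(dag$nodes, names(cpts))
  if (length(miss)) stop_("CPTs missing for: ", paste(miss, collapse = ", "))
  for (v in dag$nodes) {
    pa <- bn_parents(dag, v)
    r <- length(states[[v]])
    q <- prod(vapply(states[pa], length, 0L))
    M <- cpts[[v]]
    if (!is.matrix(M) || nrow(M) != q || ncol(M) != r)
      stop_("CPT of '", v, "' must be ", q, " x ", r)
    if (any(M < -1e-12)) stop_("CPT of '", v, "' has negative entries")
    if (any(abs(rowSums(M) - 1) > 1e-9))
      stop_("CPT rows of '", v, "' do not sum to 1")
  }
  structure(list(dag = dag, states = states[dag$nodes],
                 cpts = cpts[dag$nodes], outcome = outcome),
            class = "bayesian_network")
}

# Parents in canonical (DAG node list) order -- the CPT row order depends
# on this, so it must be deterministic.
bn_parents <- function(dag, node) {
  pa <- parents_of(dag, node)
  dag$nodes[dag$nodes %in% pa]
}

#' @export
print.bayesian_network <- function(x, ...) {
  cat("<bayesian_network> ", length(x$dag$nodes), " nodes, ",
      nrow(x$dag$edges), " edges\n", sep = "")
  invisible(x)
}

# Flatten to the representation the C++ inference core expects.
bn_flat <- function(bn) {
  nodes <- bn$dag$nodes
  cards <- vapply(bn$states, length, 0L)
  parents0 <- lapply(nodes, function(v) match(bn_parents(bn$dag, v), nodes) - 1L)
  cpts_flat <- lapply(nodes, function(v) as.numeric(t(bn$cpts[[v]])))
  list(nodes = nodes, cards = unname(cards), parents0 = parents0,
       cpts = cpts_flat)
}

# Named state assignment -> 0-based integer evidence vector (-1 = absent).
evidence_int <- function(bn, evidence) {
  nodes <- bn$dag$nodes
  ev <- rep(-1L, length(nodes))
  names(ev) <- nodes
  if (length(evidence)) {
    evidence <- unlist(evidence)
    evidence <- evidence[!is.na(evidence)]
    unknown <- setdiff(names(evidence), nodes)
    if (length(unknown)) stop_("evidence on unknown node(s): ",
                               paste(unknown, collapse = ", "))
    for (v in names(evidence)) {
      k <- match(evidence[[v]], bn$states[[v]])
      if (is.na(k)) stop_("'", evidence[[v]], "' is not a state of '", v, "'")
      ev[v] <- k - 1L
    }
  }
  ev
}

# CPT row index (1-based) for a named parent-state assignment.
cpt_row_index <- function(bn, node, assignment) {
  pa <- bn_parents(bn$dag, node)
  if (!length(pa)) return(1L)
  j <- 0L
  for (p in pa) {
    k <- match(assignment[[p]], bn$states[[p]])
    if (is.na(k)) stop_("'", assignment[[p]], "' is not a state of '", p, "'")
    j <- j * length(bn$states[[p]]) + (k - 1L)
  }
  j + 1L
}

#' Joint probability of a complete assignment
#'
#' Chain-rule product of CPT entries, accumulated in log space.
#'
#' @param bn A [bayesian_network()].
#' @param assignment Named list or character vector assigning a state to
#'   every node.
#' @return The joint probability.
#' @export
joint_probability <- function(bn, assignment) {
  assignment <- as.list(assignment)
  miss <- setdiff(bn$dag$nodes, names(assignment))
  if (length(miss)) stop_("incomplete assignment: ", paste(miss, collapse = ", "))
  lp <- 0
  for (v in bn$dag$nodes) {
    k <- match(assignment[[v]], bn$states[[v]])
    if (is.na(k)) stop_("'", assignment[[v]], "' is not a state of '", v, "'")
    lp <- lp + log(bn$cpts[[v]][cpt_row_index(bn, v, assignment), k])
  }
  exp(lp)
}

#' Posterior of a target node given partial evidence
#'
#' Exact inference by variable elimination (min-degree ordering);
#' unobserved predictors are marginalized, so missing values need no
#' imputation. Evidence with probability zero under the model raises an
#' error rather than returning `NaN`.
#'
#' @param bn A [bayesian_network()].
#' @param target Node name.
#' @param evidence Named list/vector of observed states (the target must
#'   not appear); `NULL` or empty gives the prior marginal.
#' @return Named probability vector over the target's states (sums to 1).
#' @export
query_posterior <- function(bn, target, evidence = NULL) {
  if (!target %in% bn$dag$nodes) stop_("unknown target '", target, "'")
  if (target %in% names(evidence)) stop_("target must not be in evidence")
  fl <- bn_flat(bn)
  ev <- evidence_int(bn, evidence)
  p <- cpp_posterior(fl$cards, fl$parents0, fl$cpts, unname(ev),
                     match(target, fl$nodes) - 1L)
  if (anyNA(p)) stop_("evidence has probability zero under the model")
  setNames(as.numeric(p), bn$states[[target]])
}

#' Posterior by exhaustive enumeration (test oracle)
#'
#' Enumerates the full joint distribution in R; independent of the
#' variable-elimination path and deliberately slow. Refuses state spaces
#' above `1e7`.
#'
#' @inheritParams query_posterior
#' @return Named probability vector over the target's states.
#' @export
brute_force_posterior <- function(bn, target, evidence = NULL) {
  if (target %in% names(evidence)) stop_("target must not be in evidence")
  free <- setdiff(bn$dag$nodes, names(evidence))
  size <- prod(vapply(bn$states[free], length, 0L))
  if (size > 1e7) stop_("state space too large for brute force")
  grid <- expand.grid(bn$states[free], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  ev <- as.list(evidence)
  # joint probability of every grid row, by direct CPT gathering (kept
  # independent of the variable-elimination code path)
  n <- nrow(grid)
  logp <- numeric(n)
  state_idx <- function(v) {
    if (v %in% free) match(grid[[v]], bn$states[[v]])
    else rep(match(ev[[v]], bn$states[[v]]), n)
  }
  for (v in bn$dag$nodes) {
    pa <- bn_parents(bn$dag, v)
    j <- rep(1L, n)
    for (p in pa) j <- (j - 1L) * length(bn$states[[p]]) + state_idx(p)
    logp <- logp + log(bn$cpts[[v]][cbind(j, state_idx(v))])
  }
  p <- exp(logp)
  acc <- vapply(bn$states[[target]], function(s)
    sum(p[grid[[target]] == s]), 0)
  if (sum(acc) <= 0) stop_("evidence has probability zero under the model")
  acc / sum(acc)
}

#' Predicted outcome risk for a discretized record
#'
#' Returns `P(outcome = positive state | observed predictors)`; missing
#' predictors are simply absent from the evidence.
#'
#' @param bn A [bayesian_network()] whose `outcome` is set (or supplied).
#' @param record Named list / one-row data frame of discrete states,
#'   `NA` = missing.
#' @param outcome Outcome node; defaults to the network's.
#' @return Probability of the positive (second) outcome state.
#' @export
predict_risk <- function(bn, record, outcome = bn$outcome) {
  if (is.null(outcome)) stop_("no outcome node set")
  rec <- as.list(record)
  rec <- rec[names(rec) %in% setdiff(bn$dag$nodes, outcome)]
  rec <- rec[!vapply(rec, function(x) is.na(x) || is.null(x), TRUE)]
  post <- query_posterior(bn, outcome, rec)
  unname(post[2])
}

# Batch risk prediction over a discretized cohort (C++ path).
predict_cohort <- function(bn, cohort, outcome = bn$outcome) {
  fl <- bn_flat(bn)
  m <- cohort_int_matrix(cohort, fl$nodes, bn$states)
  ti <- match(outcome, fl$nodes) - 1L
  m[, ti + 1L] <- NA_integer_
  post <- cpp_predict(fl$cards, fl$parents0, fl$cpts, m, ti)
  post[, 2]
}

# Discretized cohort -> 0-based integer matrix (NA = missing) over `nodes`.
cohort_int_matrix <- function(cohort, nodes, states) {
  d <- cohort$data
  m <- matrix(NA_integer_, nrow = nrow(d), ncol = length(nodes),
              dimnames = list(NULL, nodes))
  for (v in nodes) m[, v] <- match(d[[v]], states[[v]]) - 1L
  m
}

#' Read / write a Bayesian network as JSON
#'
#' The document bundles the structure, state spaces and CPT rows (row
#' order lexicographic over parent states in node order).
#'
#' @param path JSON file path.
#' @export
read_bn <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dag <- new_dag(raw$nodes,
                 if (!is.null(raw$edges) && NROW(raw$edges)) raw$edges)
  states <- lapply(raw$states, as.character)
  cpts <- lapply(raw$cpts, function(m) {
    m <- as.matrix(m)
    dimnames(m) <- NULL
    m
  })
  bayesian_network(dag, states, cpts, outcome = raw$outcome)
}

#' @rdname read_bn
#' @param bn A [bayesian_network()].
#' @export
write_bn <- function(bn, path) {
  doc <- list(nodes = bn$dag$nodes,
              edges = if (nrow(bn$dag$edges)) bn$dag$edges else NULL,
              states = bn$states,
              cpts = bn$cpts,
              outcome = bn$outcome)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
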