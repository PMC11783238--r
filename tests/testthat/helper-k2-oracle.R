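# Exhaustive parent-set search over predecessors of a fixed ordering:
# the independent reference for the greedy K2 search.

exhaustive_parents <- function(co, ordering, max_parents) {
  ld <- bnscreen:::learn_data(co)
  edges <- NULL
  for (pos in seq_along(ordering)) {
    v <- ordering[pos]
    preds <- ordering[seq_len(pos - 1)]
    best <- NULL
    best_score <- -Inf
    for (k in 0:min(max_parents, length(preds))) {
      sets <- if (k == 0) list(character(0)) else
        asplit(utils::combn(preds, k), 2)
      for (ps in sets) {
        sc <- bnscreen:::family_logscore_m(ld$m, ld$cards,
                                           match(v, ld$nodes),
                                           match(ps, ld$nodes))
        if (sc > best_score + 1e-9) {
          best_score <- sc
          best <- ps
        }
      }
    }
    if (length(best)) edges <- rbind(edges, cbind(unlist(best), v))
  }
  list(edges = edges)
}

total_score <- function(co, dag) {
  ld <- bnscreen:::learn_data(co)
  sum(vapply(ld$nodes, function(v)
    bnscreen:::family_logscore_m(ld$m, ld$cards, match(v, ld$nodes),
                                 match(bnscreen:::bn_parents(dag, v),
                                       ld$nodes)), 0))
}

# All permutations of a small vector (recursive, no dependency).
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in combinat_perms(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}
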