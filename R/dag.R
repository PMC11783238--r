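#' Directed acyclic graph over named variables
#'
#' @param nodes Ordered character vector of variable names. The order is
#'   the deterministic tie-break order used throughout.
#' @param edges A two-column matrix or data frame of `(parent, child)`
#'   pairs, or `NULL` for an edgeless graph.
#' @return An object of class `"bn_dag"`.
#' @export
new_dag <- function(nodes, edges = NULL) {
  if (anyDuplicated(nodes)) stop_("duplicated node names")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop_("edges must have two columns (parent, child)")
    edges <- matrix(as.character(edges), ncol = 2)
  }
  colnames(edges) <- c("parent", "child")
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown))
    stop_("edge endpoint(s) not in node set: ", paste(unknown, collapse = ", "))
  if (any(edges[, 1] == edges[, 2])) stop_("self-loop edge")
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop_("duplicate edge")
  dag <- structure(list(nodes = nodes, edges = edges), class = "bn_dag")
  topological_order(dag)  # raises on cycles
  dag
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("<bn_dag> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

parents_of <- function(dag, node) dag$edges[dag$edges[, 2] == node, 1]

children_of <- function(dag, node) dag$edges[dag$edges[, 1] == node, 2]

#' Topological order of a DAG
#'
#' Kahn's algorithm with deterministic tie-breaking by node-list order.
#' On a cycle, the error message names one offending cycle.
#'
#' @param dag A [new_dag()] (or a bare list with `nodes` and `edges`).
#' @return Character vector: every parent precedes its children.
#' @export
topological_order <- function(dag) {
  nodes <- dag$nodes
  edges <- dag$edges
  indeg <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    t <- table(edges[, 2])
    indeg[names(t)] <- as.integer(t)
  }
  order <- character(0)
  remaining <- nodes
  repeat {
    ready <- remaining[indeg[remaining] == 0]
    if (!length(ready)) break
    nxt <- ready[1]  # node-list order
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
    ch <- edges[edges[, 1] == nxt, 2]
    indeg[ch] <- indeg[ch] - 1L
  }
  if (length(remaining)) {
    # walk parent pointers inside the remaining set until a repeat
    cur <- remaining[1]
    seen <- character(0)
    while (!cur %in% seen) {
      seen <- c(seen, cur)
      cur <- intersect(edges[edges[, 2] == cur, 1], remaining)[1]
    }
    cyc <- seen[which(seen == cur):length(seen)]
    stop_("graph has a cycle: ", paste(c(cyc, cur), collapse = " -> "))
  }
  order
}

#' Read / write a DAG as a tab-separated edge list
#'
#' One `parent<TAB>child` pair per line; `#` starts a comment. An empty
#' file yields an edgeless DAG (with a warning).
#'
#' @param path Edge-list file.
#' @param nodes Node set and order; defaults to the order of first
#'   appearance in the file.
#' @return A `"bn_dag"`.
#' @export
read_dag <- function(path, nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty DAG file: ", path, call. = FALSE)
    return(new_dag(nodes %||% character(0)))
  }
  parts <- strsplit(lines, "[\t ]+")
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) stop_("malformed edge line: '", lines[which(bad)[1]], "'")
  edges <- do.call(rbind, parts)
  new_dag(nodes %||% unique(c(t(edges))), edges)
}

#' @rdname read_dag
#' @param dag A `"bn_dag"`.
#' @export
write_dag <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# parent\tchild", con)
  if (nrow(dag$edges))
    writeLines(paste(dag$edges[, 1], dag$edges[, 2], sep = "\t"), con)
  invisible(path)
}

#' Render a DAG in DOT format
#'
#' @param dag A `"bn_dag"`.
#' @return A character scalar of Graphviz DOT source.
#' @export
as_dot <- function(dag) {
  body <- c(paste0("  \"", dag$nodes, "\";"),
            if (nrow(dag$edges))
              paste0("  \"", dag$edges[, 1], "\" -> \"", dag$edges[, 2], "\";"))
  paste(c("digraph bn {", body, "}"), collapse = "\n")
}

#' Load an expert-elicited DAG over a registry's variables
#'
#' Reads an edge-list file and validates it against the registry node set;
#' nodes are ordered by the registry. The bundled default file is a
#' documented approximation of an expert consensus graph (see the file's
#' comments); users substitute their own.
#'
#' @param path Edge-list file; defaults to the bundled synthetic expert DAG.
#' @param registry A [bn_registry()].
#' @return A `"bn_dag"` over the registry variables.
#' @export
load_expert_dag <- function(path = NULL, registry = default_lc_registry()) {
  path <- path %||% system.file("extdata", "expert_dag_synthetic.tsv",
                                package = "bnscreen", mustWork = TRUE)
  dag <- read_dag(path, nodes = registry_names(registry))
  unknown <- setdiff(unique(c(dag$edges)), registry_names(registry))
  if (length(unknown))
    stop_("expert DAG uses unknown variable(s): ", paste(unknown, collapse = ", "))
  dag
}
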