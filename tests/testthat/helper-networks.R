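# Builders shared across the suite: random discrete networks, tiny
# registries and discretized cohorts constructed in code.

rand_bn <- function(V = 6, max_parents = 2, max_card = 3, seed = 1,
                    min_prob = 0.05) {
  set.seed(seed)
  nodes <- paste0("X", seq_len(V))
  cards <- sample.int(max_card - 1L, V, replace = TRUE) + 1L  # 2..max_card
  cards[1] <- 2L  # first node doubles as the binary outcome
  edges <- NULL
  for (i in seq_len(V)) {
    if (i == 1) next
    np <- sample(0:min(max_parents, i - 1), 1)
    if (np > 0)
      for (p in sample(seq_len(i - 1), np))
        edges <- rbind(edges, c(nodes[p], nodes[i]))
  }
  dag <- new_dag(nodes, edges)
  states <- lapply(cards, function(r) paste0("s", seq_len(r)))
  names(states) <- nodes
  cpts <- list()
  for (v in nodes) {
    pa <- bnscreen:::bn_parents(dag, v)
    q <- prod(vapply(states[pa], length, 0L))
    r <- length(states[[v]])
    M <- matrix(stats::rgamma(q * r, 1) + min_prob, q, r)
    cpts[[v]] <- M / rowSums(M)
  }
  bayesian_network(dag, states, cpts, outcome = nodes[1])
}

# Ancestral sampling from a network (vectorized by parent configuration);
# returns a character data frame.
sample_bn <- function(bn, n, seed = 1) {
  set.seed(seed)
  ord <- topological_order(bn$dag)
  d <- as.data.frame(setNames(rep(list(character(n)), length(ord)), ord),
                     stringsAsFactors = FALSE)
  for (v in ord) {
    pa <- bnscreen:::bn_parents(bn$dag, v)
    M <- bn$cpts[[v]]
    j <- rep(1L, n)
    for (p in pa)
      j <- (j - 1L) * length(bn$states[[p]]) + match(d[[p]], bn$states[[p]])
    for (jj in unique(j)) {
      idx <- which(j == jj)
      d[[v]][idx] <- sample(bn$states[[v]], length(idx), replace = TRUE,
                            prob = M[jj, ])
    }
  }
  d[bn$dag$nodes]
}

# Wrap a discrete data frame as a discretized cohort over a throwaway
# registry (first column is the outcome and must be binary).
as_discrete_cohort <- function(d, states = NULL) {
  nodes <- names(d)
  states <- states %||% lapply(d, function(x) sort(unique(x[!is.na(x)])))
  specs <- c(list(variable_spec(nodes[1], "outcome", states = states[[1]])),
             lapply(nodes[-1], function(v)
               variable_spec(v, "discrete", states = states[[v]], lab = FALSE)))
  reg <- bn_registry(specs)
  dd <- cbind(data.frame(id = as.character(seq_len(nrow(d))),
                         stage = rep(NA_character_, nrow(d)),
                         stringsAsFactors = FALSE), d)
  co <- bn_cohort(reg, dd, validate = FALSE)
  attr(co, "states") <- states
  co
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small continuous registry for data-model tests: outcome + sex + 3 labs.
toy_registry <- function() {
  bn_registry(
    variable_spec("LC", "outcome", states = c("non-LC", "LC")),
    variable_spec("sex", "discrete", states = c("female", "male"), lab = FALSE),
    variable_spec("ALAT", "continuous", unit = "U/L",
                  reference = list(male = c(10, 70), female = c(10, 45))),
    variable_spec("CRP", "continuous", unit = "mg/L", reference = c(NA, 6)),
    variable_spec("LDH", "continuous", unit = "U/L", reference = c(115, 255)))
}

toy_cohort <- function(n = 50, seed = 1, p_miss = 0.1) {
  set.seed(seed)
  lc <- rbinom(n, 1, 0.4)
  d <- data.frame(
    id = sprintf("r%03d", seq_len(n)),
    stage = ifelse(lc == 1, sample(c("I", "II", "III", "IV"), n, TRUE),
                   "not-applicable"),
    LC = ifelse(lc == 1, "LC", "non-LC"),
    sex = sample(c("female", "male"), n, TRUE),
    ALAT = exp(rnorm(n, 3 + 0.3 * lc, 0.4)),
    CRP = exp(rnorm(n, 1 + 0.8 * lc, 0.7)),
    LDH = exp(rnorm(n, 5.3 + 0.2 * lc, 0.25)),
    stringsAsFactors = FALSE)
  for (v in c("ALAT", "CRP", "LDH"))
    d[[v]][runif(n) < p_miss] <- NA
  bn_cohort(toy_registry(), d)
}
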