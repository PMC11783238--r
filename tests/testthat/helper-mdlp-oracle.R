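# Naive reference implementation of recursive MDL splitting, written
# directly from the definitions (quadratic loops, no shared code with the
# package implementation). Used as the brute-force oracle on small inputs.

oracle_entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_mdlp <- function(values, labels, min_bin = 2) {
  stopifnot(length(values) == length(labels))
  ord <- order(values)
  v <- values[ord]
  y <- labels[ord]
  split_rec <- function(v, y) {
    n <- length(v)
    cand <- c()
    for (i in seq_len(n - 1)) {
      if (v[i] == v[i + 1]) next
      left_grp <- y[v == v[i]]
      right_grp <- y[v == v[i + 1]]
      pure_same <- length(unique(left_grp)) == 1 &&
        length(unique(right_grp)) == 1 &&
        unique(left_grp) == unique(right_grp)
      if (!pure_same && i >= min_bin && (n - i) >= min_bin)
        cand <- c(cand, i)
    }
    if (!length(cand)) return(numeric(0))
    gains <- sapply(cand, function(i) {
      oracle_entropy(y) - (i / n) * oracle_entropy(y[1:i]) -
        ((n - i) / n) * oracle_entropy(y[(i + 1):n])
    })
    best <- cand[which.max(gains)]
    gain <- max(gains)
    k <- length(unique(y))
    k1 <- length(unique(y[1:best]))
    k2 <- length(unique(y[(best + 1):n]))
    delta <- log2(3^k - 2) -
      (k * oracle_entropy(y) - k1 * oracle_entropy(y[1:best]) -
         k2 * oracle_entropy(y[(best + 1):n]))
    if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    cut <- (v[best] + v[best + 1]) / 2
    c(split_rec(v[1:best], y[1:best]), cut,
      split_rec(v[(best + 1):n], y[(best + 1):n]))
  }
  sort(split_rec(v, y))
}
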