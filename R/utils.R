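`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(..., call. = FALSE)

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. Every stochastic operation in the package
# funnels through this so that a seed argument is both sufficient and
# non-invasive.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed and a stream label
# (polynomial string hash modulo a prime below 2^31, so it is always a
# valid R integer seed).
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- as.integer(charToRaw(key))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}
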