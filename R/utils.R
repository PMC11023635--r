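# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness goes through this,
# so library-global RNG state is never disturbed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

# Deterministic child seeds (kept below 2^31).
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

# argmax with ties broken towards the smallest index
argmax1 <- function(x) which.max(x)

# Row-wise argmax of a matrix, first (= smallest label index) on ties.
row_argmax <- function(S) max.col(S, ties.method = "first")

`%||%` <- function(a, b) if (is.null(a)) b else a
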