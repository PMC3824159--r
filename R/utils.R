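# Internal RNG helpers. All user-facing randomness flows through integer
# seeds; callers' RNG state is never disturbed.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream derivation: Lehmer-style mix kept exact in doubles
# (all intermediates < 2^53) and below 2^31 so the result is a valid R integer.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647
  x <- as.double(abs(as.integer(seed)) %% m)
  x <- (x * 48271 + 11) %% m
  for (k in seq_along(idx)) {
    x <- (x * 48271 + as.double(idx[k]) * 8121 + 28411) %% m
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
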