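# Internal helpers: seed scoping and deterministic seed derivation.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic child seed from a master seed and an integer payload
# (e.g. a replicate number or a sum over masked entry indices).
# Kept strictly below 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(master, payload = 0) {
  m <- 2147483647
  h <- (as.numeric(master) %% m) * 16807 %% m
  h <- (h + (as.numeric(payload) %% m) * 48271) %% m
  as.integer(max(1, floor(h)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
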