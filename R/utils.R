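# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

LOG_FLOOR <- 1e-10
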