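# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic fan-out of a single user seed into per-component seeds,
# kept below 2^31 so they remain valid R integers.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 9973) %% 2147483647
}

# Round half away from zero (values here are non-negative): 0.5 -> 1.
round_half_up <- function(x) floor(x + 0.5)
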