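# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive a stream-specific 32-bit seed from a master seed without consuming
# the caller's RNG. Keeps every module's randomness tied to one recipe seed.
split_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12347L) %% 2147483562L
}
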