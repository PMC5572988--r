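# Deterministic RNG scoping: all stochastic package code runs under
# with_seed() so identical (config, seed) inputs give bit-identical output
# without disturbing the caller's RNG state.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Per-slide child seed derived from a master seed and a slide index.
# Kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 100003) %% 2147483629)
}
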