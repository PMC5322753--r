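# Internal utilities: scoped RNG and per-stage seed derivation.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. Keeps every seeded routine reproducible without
# clobbering the session's random stream.
local_seed <- function(seed, expr) {
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
  expr
}

# Fan a single pipeline seed out to per-stage seeds by fixed offsets so
# stages can be re-run independently yet reproducibly. Result stays a
# valid 32-bit integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}
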