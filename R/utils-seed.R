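# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. Keeps every stochastic routine
# reproducible from a single integer without clobbering the session RNG.
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# Derive a child seed from a base seed and an index, kept inside the 32-bit
# integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% .Machine$integer.max)
}
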