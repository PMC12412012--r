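# Seed handling for the synthetic generators. Each generator is a pure
# function of its spec: the global RNG state is saved and restored, and the
# single spec seed is split into named substreams so that changing the
# amount of randomness consumed by one stage cannot shift another.

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive named sub-seeds (< 2^31) from one master seed.
substream_seeds <- function(seed, names) {
  s <- with_preserved_rng(seed, sample.int(.Machine$integer.max - 1L,
                                           length(names)))
  stats::setNames(s, names)
}
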