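# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs
# user-level randomness.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a stage-specific seed from the global one so "fields", "catch",
# "split", ... draw from independent, reproducible streams.  Kept inside
# the 32-bit integer range.
derive_seed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Sample (n-1) standard deviation; NA for a single observation.
sample_sd <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)
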