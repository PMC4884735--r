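# Internal RNG helpers.
#
# All generators and Monte Carlo routines take an explicit seed and evaluate
# under a locally-set RNG state, restoring the caller's state afterwards, so
# that the package's functions are pure in their seed arguments and never
# disturb the user's random number stream.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable derivation of per-stage child seeds from one pipeline seed.
# Keeps results < 2^31 so they remain valid R integers.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
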