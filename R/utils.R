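# Evaluate expr with a local RNG state; the caller's stream is untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fan a master seed out into n independent stage seeds (< 2^31).
splitSeed <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated-normal draws on [lo, hi] via inverse-CDF; vectorized.
rtruncn <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm((lo - mean) / sd)
  b <- stats::pnorm((hi - mean) / sd)
  u <- stats::runif(n, a, b)
  pmin(pmax(mean + sd * stats::qnorm(u), lo), hi)
}
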