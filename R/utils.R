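# Small shared numerics. Population (not sample) SD is used throughout the
# overnight summary measures; the features are descriptive statistics of the
# night itself, not estimates for a wider population of nights.

pop_sd <- function(x) {
  n <- length(x)
  if (n < 1L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Shannon entropy of a vector of counts, -sum p*log(p), with 0*log(0) = 0.
entropy_from_counts <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(base)
}

# Evaluate an expression with the RNG seeded from `seed`, restoring any
# pre-existing RNG state afterwards so library code does not disturb the
# caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derived per-unit seeds kept inside 32-bit integer range.
derive_seed <- function(base_seed, k) {
  as.integer((as.double(base_seed) * 48271 + as.double(k) * 10007) %% 2147483629)
}
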