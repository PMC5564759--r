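# Internal helpers shared across modules.

# Run expr under an explicit, isolated RNG stream. Global .Random.seed is
# restored afterwards, so no generator leaks state into user code.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr, .rng_kind = "Mersenne-Twister")
}

# Row standardization to mean 0, sd 1 (population-free: sample sd).
standardizeRows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  if (any(s == 0))
    stop("cannot standardize constant rows")
  (x - mu) / s
}

assertCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 ||
      x != round(x))
    stop("invalid config: '", name, "' must be a positive integer")
  as.integer(x)
}

# Numeric matrix with both dimnames, coercing data.frames.
asNamedMatrix <- function(x, what = "matrix") {
  x <- as.matrix(x)
  if (!is.numeric(x))
    stop(what, " must be numeric")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row and column names")
  x
}
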