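# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Truncated normal (resample beyond 2 sd), the usual transformer init.
trunc_norm <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), sd = sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

row_softmax <- function(s) {
  # subtracting the global max is row-constant, so rowwise softmax is exact
  e <- exp(s - max(s))
  e / rowSums(e)
}
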