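# Internal numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
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

# Truncated-normal initializer, sd scaled by fan-in (values beyond 2 sd
# resampled), the conventional default for gated conv blocks.
initTruncNormal <- function(n, fanIn) {
  sdv <- sqrt(2 / fanIn)
  x <- rnorm(n, 0, sdv)
  bad <- abs(x) > 2 * sdv
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sdv)
    bad <- abs(x) > 2 * sdv
  }
  x
}

# Flatten a (D,W,H,C) tensor to an N x C matrix of spatial positions.
asPositionMatrix <- function(x) {
  d <- dim(x)
  matrix(x, nrow = prod(d[1:3]), ncol = d[4])
}

# Row-wise softmax, numerically stabilised.
rowSoftmax <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

stopifnotShape <- function(ok, msg, ...) if (!ok) shapeMismatchError(msg, ...)
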