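# Brute-force oracles and shared fixtures.  The oracles deliberately use
# plain per-position loops, independent of the vectorized implementation
# paths they are used to check.

# Non-local self-attention, evaluated position by position: for each output
# position i, scores against every j, softmax over j, attention-weighted sum
# of g, then the output projection.
bruteNonlocal <- function(x, w) {
  d <- dim(x)
  N <- prod(d[1:3])
  C <- d[4]
  X <- matrix(x, N, C)
  out <- matrix(0, N, C)
  for (i in seq_len(N)) {
    ti <- as.numeric(X[i, ] %*% w$Wtheta) + w$btheta
    scores <- numeric(N)
    for (j in seq_len(N)) {
      pj <- as.numeric(X[j, ] %*% w$Wphi) + w$bphi
      scores[j] <- sum(ti * pj)
    }
    a <- exp(scores - max(scores))
    a <- a / sum(a)
    yi <- numeric(C %/% 2L)
    for (j in seq_len(N)) {
      gj <- as.numeric(X[j, ] %*% w$Wg) + w$bg
      yi <- yi + a[j] * gj
    }
    out[i, ] <- as.numeric(yi %*% w$Wz) + w$bz
    if (isTRUE(w$residual)) out[i, ] <- out[i, ] + X[i, ]
  }
  array(out, d)
}

# scSE evaluated with per-voxel loops: channel gate from the squeezed means,
# spatial gate per voxel, summed branches.
bruteScse <- function(x, wc, ws) {
  d <- dim(x)
  s <- numeric(d[4])
  for (c in seq_len(d[4])) s[c] <- mean(x[, , , c])
  h <- pmax(as.numeric(wc$W1 %*% s) + wc$b1, 0)
  gate <- 1 / (1 + exp(-(as.numeric(wc$W2 %*% h) + wc$b2)))
  out <- array(0, d)
  for (hh in seq_len(d[3])) for (ww in seq_len(d[2])) for (dd in seq_len(d[1])) {
    v <- x[dd, ww, hh, ]
    gs <- 1 / (1 + exp(-(sum(ws$w * v) + ws$b)))
    out[dd, ww, hh, ] <- gate * v + gs * v
  }
  out
}

# All-pairs symmetric 95th-percentile surface distance.  Surfaces found by
# explicit neighbour checks; distances by full pairwise enumeration.
bruteHd95 <- function(a, b, spacing = c(1, 1, 1), percentile = 0.95) {
  surfaceVoxels <- function(m) {
    d <- dim(m)
    keep <- NULL
    for (h in seq_len(d[3])) for (w in seq_len(d[2])) for (dd in seq_len(d[1])) {
      if (!m[dd, w, h]) next
      nb <- c(
        if (dd > 1) m[dd - 1, w, h] else FALSE,
        if (dd < d[1]) m[dd + 1, w, h] else FALSE,
        if (w > 1) m[dd, w - 1, h] else FALSE,
        if (w < d[2]) m[dd, w + 1, h] else FALSE,
        if (h > 1) m[dd, w, h - 1] else FALSE,
        if (h < d[3]) m[dd, w, h + 1] else FALSE
      )
      if (any(!nb) || length(nb) < 6) keep <- rbind(keep, c(dd, w, h))
    }
    keep
  }
  sa <- surfaceVoxels(a)
  sb <- surfaceVoxels(b)
  if (is.null(sa) || is.null(sb)) return(NA_real_)
  dmat <- matrix(0, nrow(sa), nrow(sb))
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb)))
    dmat[i, j] <- sqrt(sum(((sa[i, ] - sb[j, ]) * spacing)^2))
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  as.numeric(quantile(pooled, percentile, names = FALSE))
}

# A minimal two-stage configuration used where only the topology matters.
# Reduction 2 keeps the 4-channel stage's cSE bottleneck at two hidden units.
microConfig <- function(seed = 11L)
  networkConfig(inputShape = c(4L, 4L, 4L), filters = c(4L, 8L),
                scseReduction = 2L, seed = seed)

# One cached tiny phantom per test run.
tinyPhantomFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generatePhantom(tinyPhantomSpec(seed = 1L))
    cache
  }
})

randomMask <- function(dims, p = 0.2) array(runif(prod(dims)) < p, dims)
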