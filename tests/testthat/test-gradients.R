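# Finite-difference verification of the hand-derived backward pass.  The
# backward is the one piece with no library to lean on, so it is checked
# directly against central differences of the loss.

test_that("analytic gradients match central finite differences across all tensors", {
  set.seed(41)
  cfg <- microConfig()
  m <- buildNetwork(cfg)
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  lab <- array(sample(c(0L, 1L, 2L, 4L), 64, TRUE), c(4, 4, 4))
  lossOf <- function(model)
    softDiceLoss(scseVNet:::vnetForwardInternal(model, x)$probs, lab)
  fw <- scseVNet:::vnetForwardInternal(m, x, keepCache = TRUE)
  d <- dim(fw$probs)
  P <- matrix(fw$probs, prod(d[1:3]), d[4])
  G <- matrix(labelsToOneHot(lab), prod(d[1:3]), d[4])
  lg <- scseVNet:::softDiceLossGrad(P, G)
  expect_equal(lg$loss, lossOf(m), tolerance = 1e-12)
  grads <- scseVNet:::vnetBackward(m, fw$cache, lg$dLogits)
  expect_setequal(names(grads), names(m@params)) # every tensor has a gradient
  eps <- 1e-6
  for (nm in names(m@params)) {
    n <- length(m@params[[nm]])
    idx <- if (n <= 2) seq_len(n) else sample.int(n, 2)
    for (i in idx) {
      mp <- m; mp@params[[nm]][i] <- mp@params[[nm]][i] + eps
      mm <- m; mm@params[[nm]][i] <- mm@params[[nm]][i] - eps
      fd <- (lossOf(mp) - lossOf(mm)) / (2 * eps)
      an <- as.numeric(grads[[nm]])[i]
      # absolute + relative band: central differences carry ~1e-6 noise here
      expect_lt(abs(an - fd), 1e-5 + 1e-3 * abs(fd))
    }
  }
})

test_that("non-local and scSE backwards match finite differences of a linear functional", {
  set.seed(42)
  d <- c(2, 3, 2, 4)
  x <- array(rnorm(prod(d)), d)
  R <- array(rnorm(prod(d)), d)
  eps <- 1e-6
  # non-local dX
  w <- nonlocalWeights(4, residual = TRUE)
  fc <- scseVNet:::nonlocalForwardCache(x, w)
  bk <- scseVNet:::nonlocalBackward(R, w, fc$cache)
  for (i in sample.int(prod(d), 5)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (sum(nonlocalForward(xp, w) * R) - sum(nonlocalForward(xm, w) * R)) / (2 * eps)
    expect_equal(as.numeric(bk$dX)[i], fd, tolerance = 1e-4)
  }
  # scSE dX
  wc <- cseWeights(4, r = 2)
  ws <- sseWeights(4)
  fc2 <- scseVNet:::scseForwardCache(x, wc, ws)
  bk2 <- scseVNet:::scseBackward(R, wc, ws, fc2$cache)
  for (i in sample.int(prod(d), 5)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (sum(scseForward(xp, wc, ws) * R) - sum(scseForward(xm, wc, ws) * R)) / (2 * eps)
    expect_equal(as.numeric(bk2$dX)[i], fd, tolerance = 1e-4)
  }
})
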