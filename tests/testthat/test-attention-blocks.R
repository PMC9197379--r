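test_that("the channel squeeze is global average pooling to one value per channel", {
  x <- array(1:8, c(2, 2, 2, 1))
  expect_equal(cseSqueeze(x), 4.5)
  # constant channels squeeze to their constant
  x2 <- array(0, c(3, 4, 2, 3))
  x2[, , , 1] <- 2; x2[, , , 2] <- -1; x2[, , , 3] <- 7
  expect_equal(cseSqueeze(x2), c(2, -1, 7))
  # D x W x H x C -> 1 x 1 x 1 x C: length equals the channel count
  set.seed(1)
  x3 <- array(rnorm(5 * 4 * 3 * 6), c(5, 4, 3, 6))
  expect_length(cseSqueeze(x3), 6)
})

test_that("the channel excitation bottleneck gates as specified", {
  # zero weights: sigmoid(0) = 0.5 everywhere
  w0 <- cseWeights(4, r = 2, init = "zero")
  expect_equal(cseExcite(numeric(4), w0), rep(0.5, 4))
  # hand-computed 2-channel case
  w <- list(W1 = matrix(c(1, 0), 1, 2), b1 = 0,
            W2 = matrix(c(1, 0), 2, 1), b2 = c(0, 0), r = 2L)
  g <- cseExcite(c(2, 5), w)
  expect_equal(g, c(1 / (1 + exp(-2)), 0.5), tolerance = 1e-6)
  expect_equal(g[1], 0.8808, tolerance = 1e-4)
  # reduction ratio 4 gives a hidden layer of C/4 units
  w320 <- cseWeights(320, r = 4)
  expect_equal(nrow(w320$W1), 80)
  # dimension mismatch is a typed error
  expect_error(cseExcite(numeric(3), w0), class = "ShapeMismatchError")
})

test_that("the literal excitation order (sigmoid first, ReLU last) is available", {
  set.seed(2)
  w <- cseWeights(4, r = 2)
  s <- rnorm(4)
  lit <- cseExcite(s, w, order = "literal")
  expect_equal(lit, pmax(as.numeric(w$W2 %*% (1 / (1 + exp(-(w$W1 %*% s + w$b1)))) + w$b2), 0))
})

test_that("cSE and sSE with zero weights scale the input by exactly 0.5", {
  set.seed(3)
  x <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  expect_equal(cseForward(x, cseWeights(4, r = 2, init = "zero")), 0.5 * x)
  expect_equal(sseForward(x, sseWeights(4, init = "zero")), 0.5 * x)
})

test_that("zero-initialized scSE is the identity map and zero input maps to zero", {
  set.seed(4)
  x <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  wc0 <- cseWeights(4, r = 2, init = "zero")
  ws0 <- sseWeights(4, init = "zero")
  expect_equal(scseForward(x, wc0, ws0), x, tolerance = 1e-12)
  wc <- cseWeights(4, r = 2)
  ws <- sseWeights(4)
  z <- array(0, c(2, 3, 4, 4))
  expect_equal(scseForward(z, wc, ws), z)
})

test_that("scSE matches the per-voxel gating oracle on random inputs", {
  set.seed(5)
  for (i in 1:10) {
    d <- c(sample(2:4, 3, replace = TRUE), sample(c(2, 4, 8), 1))
    x <- array(rnorm(prod(d)), d)
    wc <- cseWeights(d[4], r = 2)
    ws <- sseWeights(d[4])
    expect_equal(scseForward(x, wc, ws), bruteScse(x, wc, ws),
                 tolerance = 1e-10)
  }
})

test_that("sSE reduces to a pointwise sigmoid gate for a single channel", {
  set.seed(6)
  x <- array(rnorm(27), c(3, 3, 3, 1))
  w <- list(w = matrix(1, 1, 1), b = 0)
  expect_equal(sseForward(x, w), x * (1 / (1 + exp(-x))), tolerance = 1e-12)
})

test_that("cSE/sSE gates keep outputs bounded by the input", {
  set.seed(7)
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  wc <- cseWeights(4, r = 2)
  ws <- sseWeights(4)
  expect_true(all(abs(cseForward(x, wc)) <= abs(x)))
  expect_true(all(abs(sseForward(x, ws)) <= abs(x)))
  expect_true(all(abs(scseForward(x, wc, ws)) <= 2 * abs(x)))
})

test_that("non-local projections have half the input channels and rows sum to one", {
  set.seed(8)
  w <- nonlocalWeights(8)
  expect_equal(ncol(w$Wtheta), 4)
  expect_equal(ncol(w$Wphi), 4)
  expect_equal(ncol(w$Wg), 4)
  x <- array(rnorm(2 * 2 * 2 * 8), c(2, 2, 2, 8))
  res <- nonlocalForward(x, w, returnAttention = TRUE)
  expect_equal(dim(res$attention), c(8, 8))
  expect_true(all(res$attention >= 0 & res$attention <= 1))
  expect_true(max(abs(rowSums(res$attention) - 1)) < 1e-6)
  expect_equal(dim(res$out), dim(x))
  expect_error(nonlocalWeights(5), class = "ChannelParityError")
})

test_that("a two-position toy case matches the hand-evaluated attention equations", {
  # N = 2 positions, C = 2 channels: evaluate softmax(theta phi^T) g W_z by hand
  x <- array(c(1, 3, 2, -1), c(1, 1, 2, 2)) # positions (1,3), channels 2
  w <- list(Wtheta = matrix(c(1, 0), 2, 1), btheta = 0,
            Wphi = matrix(c(1, 0), 2, 1), bphi = 0,
            Wg = matrix(c(0, 1), 2, 1), bg = 0,
            Wz = matrix(c(1, 1), 1, 2), bz = c(0, 0), residual = FALSE)
  # theta = (1, 3); phi = (1, 3); g = (2, -1)
  # scores row1 = (1, 3) -> softmax (e^1, e^3)/.; row2 = (3, 9)
  a1 <- exp(c(1, 3) - 3); a1 <- a1 / sum(a1)
  a2 <- exp(c(3, 9) - 9); a2 <- a2 / sum(a2)
  y <- c(sum(a1 * c(2, -1)), sum(a2 * c(2, -1)))
  expected <- array(c(y, y), c(1, 1, 2, 2)) # Wz broadcasts y to both channels
  expect_equal(nonlocalForward(x, w), expected, tolerance = 1e-10)
  expect_equal(nonlocalForward(x, w), bruteNonlocal(x, w), tolerance = 1e-12)
})

test_that("vectorized non-local attention equals the per-position loop oracle", {
  set.seed(9)
  for (i in 1:50) {
    d <- c(sample(1:4, 3, replace = TRUE), sample(c(2, 4, 6), 1))
    while (prod(d[1:3]) > 64) d[1:3] <- pmax(d[1:3] - 1, 1)
    x <- array(rnorm(prod(d)), d)
    w <- nonlocalWeights(d[4], residual = (i %% 2 == 0))
    expect_lt(max(abs(nonlocalForward(x, w) - bruteNonlocal(x, w))), 1e-5)
  }
})

test_that("non-local attention is equivariant under spatial permutations", {
  set.seed(10)
  d <- c(2, 3, 2, 4)
  N <- prod(d[1:3])
  x <- array(rnorm(prod(d)), d)
  w <- nonlocalWeights(4)
  perm <- sample(N)
  X <- matrix(x, N, d[4])
  xp <- array(X[perm, ], d)
  outP <- matrix(nonlocalForward(xp, w), N, d[4])
  out <- matrix(nonlocalForward(x, w), N, d[4])
  expect_equal(outP, out[perm, ], tolerance = 1e-10)
})

test_that("all three blocks preserve the input shape", {
  set.seed(11)
  d <- c(3, 5, 2, 4)
  x <- array(rnorm(prod(d)), d)
  expect_equal(dim(cseForward(x, cseWeights(4, r = 2))), d)
  expect_equal(dim(sseForward(x, sseWeights(4))), d)
  expect_equal(dim(scseForward(x, cseWeights(4, r = 2), sseWeights(4))), d)
  expect_equal(dim(nonlocalForward(x, nonlocalWeights(4))), d)
})
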