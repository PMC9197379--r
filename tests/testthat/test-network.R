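test_that("the default shape trace reproduces the published 10-layer table", {
  tr <- shapeTrace(defaultNetworkConfig())
  expected <- data.frame(
    layer = 0:9,
    D = c(64, 64, 32, 16, 8, 4, 8, 16, 32, 64),
    W = c(128, 128, 64, 32, 16, 8, 16, 32, 64, 128),
    H = c(128, 128, 64, 32, 16, 8, 16, 32, 64, 128),
    C = c(4, 20, 40, 80, 160, 320, 160, 80, 40, 20)
  )
  expect_equal(tr[, c("layer", "D", "W", "H", "C")], expected)
  expect_equal(sum(tr$path %in% c("encoder", "bottleneck")), 5) # five encoding stages
  expect_equal(sum(tr$path == "decoder"), 4)                    # four decoding stages
})

test_that("each encoder downsample halves the spatial extents and doubles channels", {
  tr <- shapeTrace(defaultNetworkConfig())
  enc <- tr[tr$path %in% c("encoder", "bottleneck"), ]
  for (i in seq_len(nrow(enc) - 1)) {
    expect_equal(enc$D[i + 1] * 2, enc$D[i])
    expect_equal(enc$W[i + 1] * 2, enc$W[i])
    expect_equal(enc$H[i + 1] * 2, enc$H[i])
    expect_equal(enc$C[i + 1], enc$C[i] * 2)
  }
})

test_that("a broken filter-doubling chain is rejected naming the stage", {
  err <- tryCatch(
    networkConfig(filters = c(20L, 40L, 100L, 160L, 320L)),
    error = identity
  )
  expect_s3_class(err, "ConfigError")
  expect_match(conditionMessage(err), "stage 3")
})

test_that("the layer table mirrors the architecture: all conv, no pooling", {
  st <- stageTable(defaultNetworkConfig())
  expect_equal(nrow(st), 10)
  expect_true(all(st$type == "conv"))
  expect_true(all(st$kernel == "3x3x3"))
  expect_true(all(st$activation == "ReLU"))
  expect_equal(st$scse, c(FALSE, rep(TRUE, 9)))     # stem has no scSE
  expect_equal(st$nonlocal, seq_len(10) == 6)       # only the bottleneck
  expect_equal(st$convLayers, c(1, 1, rep(2, 8)))
  expect_equal(st$filters, c(20, 20, 40, 80, 160, 320, 160, 80, 40, 20))
})

test_that("forward output is a per-voxel probability simplex of the input's size", {
  m <- buildNetwork(microConfig())
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  p <- vnetForward(m, x)
  expect_equal(dim(p), c(4, 4, 4, 4))
  expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-6)
  expect_true(all(p >= 0))
  expect_error(vnetForward(m, array(0, c(5, 4, 4, 4))),
               class = "ShapeMismatchError")
})

test_that("forward is deterministic in evaluation mode", {
  m <- buildNetwork(microConfig())
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  expect_identical(vnetForward(m, x), vnetForward(m, x))
})

test_that("identical seeds build identical networks", {
  m1 <- buildNetwork(microConfig(seed = 5L))
  m2 <- buildNetwork(microConfig(seed = 5L))
  expect_identical(m1@params, m2@params)
  m3 <- buildNetwork(microConfig(seed = 6L))
  expect_false(identical(m1@params, m3@params))
})

test_that("zeroing a stage's convolutions and scSE makes the stage an identity map", {
  m <- buildNetwork(microConfig())
  for (nm in names(m@params))
    if (grepl("^enc2\\.", nm)) m@params[[nm]][] <- 0
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  fw <- scseVNet:::vnetForwardInternal(m, x, keepCache = TRUE)
  # with zero convs, conv output is 0, zero-init scSE passes 0 through, and
  # the residual addition returns the stage input unchanged
  expect_equal(fw$cache$encOut[[2]], fw$cache$encIn[[2]], tolerance = 1e-12)
})

test_that("one optimization step moves every trainable tensor", {
  set.seed(21)
  m <- buildNetwork(microConfig())
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  lab <- array(sample(c(0L, 1L, 2L, 4L), 64, TRUE), c(4, 4, 4))
  st <- scseVNet:::adamInit(m@params)
  res <- scseVNet:::trainStep(m, x, lab, st, lr = 1e-3)
  moved <- vapply(names(m@params), function(nm)
    any(res$model@params[[nm]] != m@params[[nm]]), TRUE)
  expect_true(all(moved))
})

test_that("concat skip fusion doubles the decoder input channels in the trace", {
  cfg <- networkConfig(inputShape = c(8L, 8L, 8L), filters = c(4L, 8L),
                      skipFusion = "concat")
  tr <- shapeTrace(cfg)
  expect_equal(tr$C[tr$path == "decoder"], 8)
  m <- buildNetwork(cfg)
  x <- array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  p <- vnetForward(m, x)
  expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-6)
})
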