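test_that("region composition follows the standard BraTS unions by default", {
  lab <- array(0L, c(5, 4, 3))
  lab[1:5] <- 1L; lab[6:12] <- 2L; lab[13:15] <- 4L # counts 1:5, 2:7, 4:3
  rm <- regionMasks(lab)
  expect_equal(sum(rm$WT), 15) # {1,2,4}
  expect_equal(sum(rm$TC), 8)  # {1,4}
  expect_equal(sum(rm$ET), 3)  # {4}
  # literal mode maps each region to a single label
  rl <- regionMasks(lab, "literal_paper")
  expect_equal(sum(rl$WT), 3)
  expect_equal(sum(rl$TC), 5)
  expect_equal(sum(rl$ET), 7)
  expect_error(regionMasks(array(3L, c(2, 2, 2))), class = "LabelDomainError")
})

test_that("regions are nested (ET within TC within WT) for any valid labels", {
  set.seed(31)
  for (i in 1:20) {
    lab <- array(sample(c(0L, 1L, 2L, 4L), 60, TRUE), c(5, 4, 3))
    rm <- regionMasks(lab)
    expect_true(all(rm$TC[rm$ET]))
    expect_true(all(rm$WT[rm$TC]))
  }
})

test_that("an all-background grid yields three empty masks", {
  rm <- regionMasks(array(0L, c(3, 3, 3)))
  expect_equal(sum(rm$ET) + sum(rm$WT) + sum(rm$TC), 0)
})

test_that("Dice matches hand-counted overlaps and flags the empty-empty case", {
  a <- array(FALSE, c(4, 4, 1)); a[1:4] <- TRUE
  b <- array(FALSE, c(4, 4, 1)); b[3:4] <- TRUE
  expect_equal(diceCoefficient(a, b), 2 * 2 / (4 + 2)) # overlap 2 of |4|,|2|
  expect_equal(diceCoefficient(a, a), 1)
  disj <- array(FALSE, c(4, 4, 1)); disj[9:10] <- TRUE
  expect_equal(diceCoefficient(a, disj), 0)
  expect_true(is.na(diceCoefficient(a & FALSE, b & FALSE)))
  expect_error(diceCoefficient(a, array(FALSE, c(2, 2, 2))),
               class = "ShapeMismatchError")
})

test_that("sensitivity and specificity match hand-counted confusion matrices", {
  gt <- array(FALSE, c(5, 4, 1)); gt[1:10] <- TRUE
  pred <- array(FALSE, c(5, 4, 1)); pred[1:8] <- TRUE
  ss <- sensitivitySpecificity(pred, gt)
  expect_equal(ss[["sensitivity"]], 0.8) # 8 of 10 positives found
  expect_equal(ss[["specificity"]], 1.0) # no false positives
  expect_equal(sensitivitySpecificity(gt, gt), c(sensitivity = 1, specificity = 1))
  allpos <- array(TRUE, c(5, 4, 1))
  expect_equal(sensitivitySpecificity(allpos, gt)[["specificity"]], 0)
  expect_true(is.na(sensitivitySpecificity(allpos, allpos)[["specificity"]]))
})

test_that("HD95 basics: identity, single-voxel distance, symmetry, spacing", {
  a <- array(FALSE, c(8, 8, 8)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[5, 2, 2] <- TRUE
  expect_equal(hausdorff95(a, b), 3)
  expect_equal(hausdorff95(a, a), 0)
  expect_equal(hausdorff95(a, b, spacing = c(2, 1, 1)), 6)
  set.seed(32)
  for (i in 1:5) {
    m1 <- randomMask(c(6, 6, 6), 0.3)
    m2 <- randomMask(c(6, 6, 6), 0.3)
    if (!any(m1) || !any(m2)) next
    expect_equal(hausdorff95(m1, m2), hausdorff95(m2, m1))
  }
  expect_true(is.na(hausdorff95(a & FALSE, b)))
})

test_that("distance-transform HD95 equals the all-pairs surface oracle", {
  set.seed(33)
  for (i in 1:20) {
    dims <- sample(5:16, 3, replace = TRUE)
    sp <- if (i %% 4 == 0) runif(3, 0.5, 3) else c(1, 1, 1)
    m1 <- randomMask(dims, runif(1, 0.1, 0.4))
    m2 <- randomMask(dims, runif(1, 0.1, 0.4))
    if (!any(m1) || !any(m2)) next
    expect_equal(hausdorff95(m1, m2, sp), bruteHd95(m1, m2, sp),
                 tolerance = 1e-6)
  }
})

test_that("soft Dice loss is ~0 at the exact one-hot prediction", {
  set.seed(34)
  lab <- array(sample(c(0L, 1L, 2L, 4L), 27, TRUE), c(3, 3, 3))
  probs <- labelsToOneHot(lab)
  expect_lt(softDiceLoss(probs, lab), 1e-4)
})

test_that("soft Dice at a uniform prediction matches the closed-form value", {
  lab <- array(0L, c(2, 2, 2)) # all background
  probs <- array(0.25, c(2, 2, 2, 4))
  eps <- 1e-5
  # class 1: 2*sum(0.25*1)+eps over sum(p)+sum(g)+eps = (4+eps)/(10+eps)
  # classes 2..4: eps / (2+eps)
  expected <- 1 - mean(c((4 + eps) / (10 + eps), rep(eps / (2 + eps), 3)))
  expect_equal(softDiceLoss(probs, lab), expected, tolerance = 1e-12)
})

test_that("soft Dice decreases monotonically from uniform to one-hot", {
  set.seed(35)
  lab <- array(sample(c(0L, 1L, 2L, 4L), 27, TRUE), c(3, 3, 3))
  onehot <- labelsToOneHot(lab)
  uniform <- array(0.25, dim(onehot))
  losses <- vapply(seq(0, 1, length.out = 5), function(t)
    softDiceLoss((1 - t) * uniform + t * onehot, lab), 0)
  expect_true(all(diff(losses) < 0))
})

test_that("soft Dice loss at one-hot truth equals 1 - mean per-class hard Dice", {
  set.seed(36)
  lab <- array(sample(c(0L, 1L, 2L, 4L), 64, TRUE), c(4, 4, 4))
  pred <- array(sample(c(0L, 1L, 2L, 4L), 64, TRUE), c(4, 4, 4))
  probs <- labelsToOneHot(pred)
  hard <- vapply(c(0L, 1L, 2L, 4L), function(k) {
    dk <- diceCoefficient(pred == k, lab == k)
    if (is.na(dk)) 1 else dk # eps makes empty-empty classes score ~1
  }, 0)
  expect_equal(softDiceLoss(probs, lab), 1 - mean(hard), tolerance = 1e-3)
})

test_that("evaluatePair reports all four indexes per region with NA for absent regions", {
  v <- tinyPhantomFixture()
  lab <- labelVolume(v)
  met <- evaluatePair(lab, lab, caseId = "self")
  expect_equal(nrow(met), 3)
  expect_equal(met$dice, rep(1, 3))
  expect_equal(met$hd95, rep(0, 3))
  noET <- lab; noET[noET == 4L] <- 1L
  met2 <- evaluatePair(noET, noET)
  expect_true(is.na(met2$dice[met2$region == "ET"]))
  expect_true(is.na(met2$hd95[met2$region == "ET"]))
  expect_equal(met2$dice[met2$region == "WT"], 1)
})
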