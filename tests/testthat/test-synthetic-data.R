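test_that("phantom generation is a pure function of the spec (bitwise reproducible)", {
  spec <- tinyPhantomSpec(seed = 9L)
  v1 <- generatePhantom(spec)
  v2 <- generatePhantom(spec)
  for (m in c("flair", "t1", "t1ce", "t2"))
    expect_identical(modality(v1, m), modality(v2, m))
  expect_identical(labelVolume(v1), labelVolume(v2))
  v3 <- generatePhantom(tinyPhantomSpec(seed = 10L))
  expect_false(identical(modality(v1, "flair"), modality(v3, "flair")))
})

test_that("phantom labels are in {0,1,2,4} and the tumor regions are nested", {
  v <- tinyPhantomFixture()
  lab <- labelVolume(v)
  expect_true(all(lab %in% c(0L, 1L, 2L, 4L)))
  expect_true(all(c(1L, 2L, 4L) %in% lab)) # all three tumor shells present
  rm <- regionMasks(lab)
  expect_true(all(rm$TC[rm$ET]))
  expect_true(all(rm$WT[rm$TC]))
})

test_that("a noiseless phantom is piecewise constant at the intensity table values", {
  it <- defaultIntensityTable()
  it["flair", ] <- c(0, 100, 140, 120, 180)
  spec <- phantomSpec(shape = c(32L, 32L, 24L), brainRadiusFrac = 0.85,
                      tumorCenter = c(18, 17, 13),
                      regionRadii = list(edema = c(9, 8, 7),
                                         core = c(6, 5.5, 4.5),
                                         enhancing = c(3, 3, 2.5)),
                      intensityTable = it, noiseSigma = 0)
  v <- generatePhantom(spec)
  fl <- modality(v, "flair")
  lab <- labelVolume(v)
  brain <- modality(v, "t1") != 0
  expect_setequal(unique(as.vector(fl)), c(0, 100, 140, 120, 180))
  expect_true(all(fl[lab == 2L] == 140)) # edema shell
  expect_true(all(fl[lab == 1L] == 120)) # core shell
  expect_true(all(fl[lab == 4L] == 180)) # enhancing centre
  expect_true(all(fl[brain & lab == 0L] == 100))
  expect_true(all(fl[!brain & lab == 0L] == 0)) # background exactly zero
  # per-class variance is exactly zero without noise
  for (k in c(1L, 2L, 4L)) expect_equal(var(fl[lab == k]), 0)
})

test_that("background voxels are exactly zero even with noise", {
  v <- tinyPhantomFixture()
  brainField <- scseVNet:::ellipsoidField(dim(v), dim(v) / 2,
                                          0.85 * dim(v) / 2)
  outside <- brainField > 1
  for (m in c("flair", "t1", "t1ce", "t2"))
    expect_true(all(modality(v, m)[outside] == 0))
})

test_that("Z-score normalization preserves the ordering of class mean intensities", {
  v <- tinyPhantomFixture()
  lab <- labelVolume(v)
  classMeans <- function(x) vapply(c(0L, 1L, 2L, 4L), function(k)
    mean(x[lab == k]), 0)
  raw <- classMeans(modality(v, "t1ce"))
  norm <- classMeans(modality(normalizeCase(v), "t1ce"))
  expect_equal(order(raw), order(norm)) # affine maps preserve order
})

test_that("a tumor poking outside the brain is rejected", {
  expect_error(
    phantomSpec(shape = c(32L, 32L, 24L), tumorCenter = c(30, 30, 22),
                regionRadii = list(edema = c(9, 8, 7), core = c(6, 5, 4),
                                   enhancing = c(3, 3, 2))),
    class = "ConfigError")
})

test_that("region radii must strictly decrease", {
  expect_error(
    phantomSpec(shape = c(32L, 32L, 24L), tumorCenter = c(16, 16, 12),
                regionRadii = list(edema = c(5, 5, 5), core = c(6, 5, 4),
                                   enhancing = c(3, 3, 2))),
    "decrease")
})

test_that("generateDataset writes n loadable cases with a reproducible manifest", {
  dir1 <- withr::local_tempdir()
  man1 <- generateDataset(3, dir1, seed = 4L)
  expect_length(man1, 3)
  dirs <- list.dirs(dir1, recursive = FALSE)
  expect_length(dirs, 3)
  for (d in dirs) {
    v <- loadCase(d)
    expect_true(hasLabels(v))
    expect_true(validObject(v))
  }
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  # same seed, fresh directory: identical per-file checksums
  dir2 <- withr::local_tempdir()
  man2 <- generateDataset(3, dir2, seed = 4L)
  expect_identical(lapply(man1, `[[`, "checksums"),
                   lapply(man2, `[[`, "checksums"))
  # different seed: different content
  dir3 <- withr::local_tempdir()
  man3 <- generateDataset(3, dir3, seed = 5L)
  expect_false(identical(lapply(man1, `[[`, "checksums"),
                         lapply(man3, `[[`, "checksums")))
})
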