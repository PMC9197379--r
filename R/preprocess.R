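#' Z-score intensity normalization
#'
#' Standardizes a volume to zero mean and unit standard deviation using the
#' population (1/N) form of the standard deviation, computed either over the
#' whole volume or over nonzero voxels only (skull-stripped backgrounds are
#' zero-heavy, so brain-only statistics are sometimes preferred).  With
#' \code{"nonzero_only"}, background voxels are passed through the same affine
#' transform as the rest of the volume.
#'
#' @param x numeric 3-D array.
#' @param maskPolicy voxels over which the statistics are computed:
#'   \code{"whole_volume"} (default) or \code{"nonzero_only"}.
#' @return A list: \code{values} (the standardized array) and \code{stats},
#'   a list with \code{mu}, \code{sigma} (population), and \code{n} (number of
#'   voxels used).
#' @examples
#' z <- zscoreNormalize(array(rnorm(64, 10, 3), c(4, 4, 4)))
#' c(mean(z$values), sd(z$values))
#' @export
zscoreNormalize <- function(x, maskPolicy = c("whole_volume", "nonzero_only")) {
  maskPolicy <- match.arg(maskPolicy)
  if (length(x) == 0) degenerateInputError("empty volume")
  sel <- if (maskPolicy == "nonzero_only") x[x != 0] else as.vector(x)
  n <- length(sel)
  if (n < 1) degenerateInputError("no voxels selected by mask policy")
  mu <- mean(sel)
  sigma <- sqrt(sum((sel - mu)^2) / n)
  if (sigma == 0) degenerateInputError("zero variance: constant image")
  list(values = (x - mu) / sigma,
       stats = list(mu = mu, sigma = sigma, n = n))
}

#' @describeIn zscoreNormalize normalize each modality of a case
#'   independently, returning a new \linkS4class{MultiModalVolume}.
#' @param vol a \linkS4class{MultiModalVolume}.
#' @export
normalizeCase <- function(vol, maskPolicy = c("whole_volume", "nonzero_only")) {
  maskPolicy <- match.arg(maskPolicy)
  MultiModalVolume(
    flair = zscoreNormalize(modality(vol, "flair"), maskPolicy)$values,
    t1    = zscoreNormalize(modality(vol, "t1"),    maskPolicy)$values,
    t1ce  = zscoreNormalize(modality(vol, "t1ce"),  maskPolicy)$values,
    t2    = zscoreNormalize(modality(vol, "t2"),    maskPolicy)$values,
    labels = labelVolume(vol), caseId = caseId(vol),
    spacing = voxelSpacing(vol)
  )
}

# Internal tensor order is (depth, width, height, channel): depth is the NIfTI
# third axis, so an (X, Y, Z) case becomes a (Z, X, Y, 4) tensor with channel
# order (flair, t1, t1ce, t2).
toInternal <- function(a) aperm(a, c(3, 1, 2))
fromInternal <- function(a) aperm(a, c(2, 3, 1))

#' Stack a case into the model input tensor
#'
#' Packs the four modalities into a single 4-D tensor in internal order
#' (depth, width, height, channel), channel order (flair, t1, t1ce, t2);
#' depth is the NIfTI third axis.
#'
#' @param vol a \linkS4class{MultiModalVolume}.
#' @return Numeric array (D, W, H, 4).
#' @export
inputTensor <- function(vol) {
  d <- dim(vol)
  out <- array(0, c(d[3], d[1], d[2], 4))
  out[, , , 1] <- toInternal(modality(vol, "flair"))
  out[, , , 2] <- toInternal(modality(vol, "t1"))
  out[, , , 3] <- toInternal(modality(vol, "t1ce"))
  out[, , , 4] <- toInternal(modality(vol, "t2"))
  out
}

perAxisStarts <- function(L, P, s) {
  if (P > L) patchTooLargeError("patch extent %d exceeds volume extent %d", P, L)
  if (s > P) # a stride beyond the patch extent would leave holes between patches
    configError("stride %d exceeds patch extent %d: tiling would not cover the volume", s, P)
  starts <- seq(0L, L - P, by = s)
  if (starts[length(starts)] != L - P) starts <- c(starts, L - P)
  as.integer(starts)
}

#' Build the deterministic patch grid over a volume
#'
#' Per axis, patch origins are the stride multiples \{0, s, 2s, ...\} that fit
#' inside the volume, plus the clamped tail origin \code{L - P} when the last
#' stride multiple falls short of it, so that the union of patches covers
#' every voxel.  Origins are returned sorted lexicographically, 0-based, in
#' internal (depth, width, height) order.
#'
#' @param volumeShape integer length-3 volume extents (depth, width, height).
#' @param patchShape integer length-3 patch extents; default (64, 128, 128).
#' @param stride integer length-3 stride; default (15, 25, 25).
#' @return A \linkS4class{PatchGrid}.
#' @examples
#' g <- buildPatchGrid(c(155, 240, 240))
#' nPatches(g) # 288
#' @export
buildPatchGrid <- function(volumeShape, patchShape = c(64L, 128L, 128L),
                           stride = c(15L, 25L, 25L)) {
  volumeShape <- as.integer(volumeShape)
  patchShape <- as.integer(patchShape)
  stride <- as.integer(stride)
  sd <- perAxisStarts(volumeShape[1], patchShape[1], stride[1])
  sw <- perAxisStarts(volumeShape[2], patchShape[2], stride[2])
  sh <- perAxisStarts(volumeShape[3], patchShape[3], stride[3])
  grid <- expand.grid(h = sh, w = sw, d = sd) # lexicographic in (d, w, h)
  org <- as.matrix(grid[, c("d", "w", "h")])
  dimnames(org) <- NULL
  new("PatchGrid", patchShape = patchShape, stride = stride,
      origins = org, volumeShape = volumeShape)
}

# Crop patch i (1-based index into the grid) out of a (D,W,H,...) tensor.
cropAt <- function(tensor, grid, i) {
  o <- grid@origins[i, ]
  p <- grid@patchShape
  if (length(dim(tensor)) == 4L)
    tensor[(o[1] + 1):(o[1] + p[1]), (o[2] + 1):(o[2] + p[2]),
           (o[3] + 1):(o[3] + p[3]), , drop = FALSE]
  else
    tensor[(o[1] + 1):(o[1] + p[1]), (o[2] + 1):(o[2] + p[2]),
           (o[3] + 1):(o[3] + p[3]), drop = FALSE]
}

#' Extract model-input patches from a case
#'
#' Crops the case's stacked 4-channel tensor (and, when labels are present,
#' the aligned label crops) at every grid origin.
#'
#' @param vol a \linkS4class{MultiModalVolume} (normalize first with
#'   [normalizeCase()] for model input).
#' @param grid a \linkS4class{PatchGrid} built for this volume's internal
#'   shape.
#' @param indices which patches to extract (default: all).
#' @return A list with one element per requested origin, each a list holding
#'   \code{tensor} (pd, pw, ph, 4), \code{origin} (0-based), and
#'   \code{labels} (pd, pw, ph integer crop, or \code{NULL}).
#' @export
extractPatches <- function(vol, grid, indices = seq_len(nPatches(grid))) {
  d <- dim(vol)
  internalShape <- c(d[3], d[1], d[2])
  stopifnotShape(identical(as.integer(internalShape), grid@volumeShape),
                 "grid built for shape %s but volume has internal shape %s",
                 paste(grid@volumeShape, collapse = "x"),
                 paste(internalShape, collapse = "x"))
  x <- inputTensor(vol)
  lab <- if (hasLabels(vol)) toInternal(labelVolume(vol)) else NULL
  lapply(indices, function(i) {
    list(tensor = cropAt(x, grid, i),
         origin = grid@origins[i, ],
         labels = if (!is.null(lab)) cropAt(lab, grid, i) else NULL)
  })
}

#' Stitch per-patch class probabilities back into a volume
#'
#' Each voxel's stitched probability is the arithmetic mean of its value over
#' all patches covering it, renormalized per voxel to sum to one.
#'
#' @param patches either a list of probability arrays
#'   (pd, pw, ph, nClasses), one per grid origin in order, or a function
#'   \code{f(i)} returning the i-th such array (useful when materializing all
#'   patches would be too large).
#' @param grid the \linkS4class{PatchGrid} the patches were extracted with.
#' @param nClasses number of classes (default 4).
#' @return Probability array (D, W, H, nClasses) in internal order; rows sum
#'   to one at every voxel.
#' @seealso [probsToLabels()] for the argmax label map.
#' @export
stitchPatches <- function(patches, grid, nClasses = 4L) {
  n <- nPatches(grid)
  getPatch <- if (is.function(patches)) patches else {
    if (length(patches) != n)
      shapeMismatchError("got %d patches for %d grid origins",
                         length(patches), n)
    function(i) patches[[i]]
  }
  vs <- grid@volumeShape
  p <- grid@patchShape
  acc <- array(0, c(vs, nClasses))
  cnt <- array(0, vs)
  for (i in seq_len(n)) {
    pp <- getPatch(i)
    if (!identical(dim(pp), as.integer(c(p, nClasses))))
      shapeMismatchError("patch %d has shape %s, expected %s", i,
                         paste(dim(pp), collapse = "x"),
                         paste(c(p, nClasses), collapse = "x"))
    o <- grid@origins[i, ]
    di <- (o[1] + 1):(o[1] + p[1])
    wi <- (o[2] + 1):(o[2] + p[2])
    hi <- (o[3] + 1):(o[3] + p[3])
    acc[di, wi, hi, ] <- acc[di, wi, hi, , drop = FALSE] + pp
    cnt[di, wi, hi] <- cnt[di, wi, hi] + 1
  }
  for (k in seq_len(nClasses)) acc[, , , k] <- acc[, , , k] / cnt
  tot <- array(0, vs)
  for (k in seq_len(nClasses)) tot <- tot + acc[, , , k]
  for (k in seq_len(nClasses)) acc[, , , k] <- acc[, , , k] / tot
  acc
}

# The class axis maps channels 1..4 to labels (0, 1, 2, 4).
classLabels <- c(0L, 1L, 2L, 4L)

#' One-hot encode a BraTS label grid
#'
#' @param labels integer array with values in \{0, 1, 2, 4\}.
#' @return Numeric array \code{c(dim(labels), 4)}; channels correspond to
#'   labels 0, 1, 2, 4 in order.
#' @export
labelsToOneHot <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), classLabels)
  if (length(bad))
    labelDomainError("label values outside {0,1,2,4}: %s",
                     paste(bad, collapse = ", "))
  d <- dim(labels)
  m <- matrix(0, prod(d), 4L)
  lv <- as.vector(labels)
  for (k in seq_along(classLabels)) m[lv == classLabels[k], k] <- 1
  array(m, c(d, 4L))
}

#' Argmax label map from class probabilities
#'
#' @param probs array (D, W, H, 4), channels for labels 0, 1, 2, 4.
#' @return Integer array (D, W, H) with values in \{0, 1, 2, 4\} (channel 4,
#'   i.e. class index 3 in 0-based terms, is written as label 4).
#' @export
probsToLabels <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, nrow = prod(d[1:3]), ncol = d[4])
  array(classLabels[max.col(m, ties.method = "first")], dim = d[1:3])
}
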