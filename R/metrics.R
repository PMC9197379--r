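# Region remapping and the four evaluation indexes: Dice, sensitivity,
# specificity, and the 95th-percentile Hausdorff surface distance.

#' Compose ET/WT/TC region masks from a BraTS label grid
#'
#' Under the standard BraTS composition (default), the evaluation regions are
#' unions of the raw labels: whole tumor WT = \{1, 2, 4\}, tumor core
#' TC = \{1, 4\}, enhancing tumor ET = \{4\}, which makes the regions nested
#' (ET within TC within WT).  \code{mode = "literal_paper"} instead maps each
#' region to a single label (WT = \{4\}, TC = \{1\}, ET = \{2\}), an
#' alternative reading of the label glossary in which the regions are
#' disjoint.
#'
#' @param labels integer array with values in \{0, 1, 2, 4\}.
#' @param mode \code{"standard"} (default) or \code{"literal_paper"}.
#' @return A list of three logical arrays: \code{ET}, \code{WT}, \code{TC}.
#' @export
regionMasks <- function(labels, mode = c("standard", "literal_paper")) {
  mode <- match.arg(mode)
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L, 4L))
  if (length(bad))
    labelDomainError("label values outside {0,1,2,4}: %s",
                     paste(bad, collapse = ", "))
  d <- dim(labels)
  asMask <- function(v) array(labels %in% v, d)
  if (mode == "standard")
    list(ET = asMask(4L), WT = asMask(c(1L, 2L, 4L)), TC = asMask(c(1L, 4L)))
  else
    list(ET = asMask(2L), WT = asMask(4L), TC = asMask(1L))
}

checkPair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    shapeMismatchError("mask shapes differ: %s vs %s",
                       paste(dim(pred), collapse = "x"),
                       paste(dim(gt), collapse = "x"))
}

#' Dice overlap coefficient of two binary masks
#'
#' \code{2 |A n B| / (|A| + |B|)}.  When both masks are empty the coefficient
#' is undefined and \code{NA} is returned (reported separately rather than
#' scored as 0, since absent regions are a property of the case, not a
#' segmentation failure).
#'
#' @param pred,gt logical (or 0/1) arrays of identical shape.
#' @return A fraction in [0, 1], or \code{NA} if both masks are empty.
#' @export
diceCoefficient <- function(pred, gt) {
  checkPair(pred, gt)
  pred <- as.logical(pred); gt <- as.logical(gt)
  sp <- sum(pred); sg <- sum(gt)
  if (sp + sg == 0) return(NA_real_)
  2 * sum(pred & gt) / (sp + sg)
}

#' Sensitivity and specificity of a binary segmentation
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP).  A zero
#' denominator (no positive, respectively no negative, ground-truth voxels)
#' yields \code{NA}.
#'
#' @inheritParams diceCoefficient
#' @return Named numeric vector \code{c(sensitivity, specificity)}.
#' @export
sensitivitySpecificity <- function(pred, gt) {
  checkPair(pred, gt)
  pred <- as.logical(pred); gt <- as.logical(gt)
  tp <- sum(pred & gt); fn <- sum(!pred & gt)
  tn <- sum(!pred & !gt); fp <- sum(pred & !gt)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' 95th-percentile Hausdorff surface distance
#'
#' Surface voxels are mask voxels with at least one background face-neighbour
#' (6-connectivity; outside the volume counts as background).  Directed
#' distances from every surface voxel of each mask to the nearest surface
#' voxel of the other are pooled symmetrically, and the 95th percentile of
#' the pooled set is returned, in physical units.  Distances are computed
#' with a separable anisotropic Euclidean distance transform.
#'
#' @inheritParams diceCoefficient
#' @param spacing voxel spacing in mm (length 3), in the axis order of the
#'   mask arrays.
#' @param percentile quantile of the pooled distances (default 0.95).
#' @return Distance in mm, or \code{NA} if either mask is empty.
#' @export
hausdorff95 <- function(pred, gt, spacing = c(1, 1, 1), percentile = 0.95) {
  checkPair(pred, gt)
  d <- dim(pred)
  pred <- array(as.logical(pred), d); gt <- array(as.logical(gt), d)
  if (!any(pred) || !any(gt)) return(NA_real_)
  sp <- cpp_surface(pred, d)
  sg <- cpp_surface(gt, d)
  dToG <- sqrt(cpp_edt_sq(sg, d, as.numeric(spacing)))
  dToP <- sqrt(cpp_edt_sq(sp, d, as.numeric(spacing)))
  pooled <- c(dToG[sp], dToP[sg])
  as.numeric(quantile(pooled, percentile, names = FALSE))
}

#' Soft Dice loss over class probabilities
#'
#' Differentiable multi-class Dice loss used for training:
#' \code{1 - mean_k (2 sum(p_k g_k) + eps) / (sum(p_k) + sum(g_k) + eps)}
#' with \code{eps = 1e-5}, where \code{g} is the one-hot encoding of the
#' labels.  By default the mean runs over all classes including background.
#'
#' @param probs array (D, W, H, 4) of class probabilities (channels for
#'   labels 0, 1, 2, 4), summing to one per voxel.
#' @param labels integer array (D, W, H) with values in \{0, 1, 2, 4\}.
#' @param eps smoothing constant.
#' @param includeBackground include the background class in the mean
#'   (default \code{TRUE}).
#' @return Scalar loss.
#' @export
softDiceLoss <- function(probs, labels, eps = 1e-5, includeBackground = TRUE) {
  d <- dim(probs)
  if (!identical(as.integer(d[1:3]), as.integer(dim(labels))))
    shapeMismatchError("probability and label shapes differ")
  P <- matrix(probs, prod(d[1:3]), d[4])
  G <- matrix(labelsToOneHot(labels), prod(d[1:3]), d[4])
  ks <- if (includeBackground) seq_len(d[4]) else 2:d[4]
  sdk <- vapply(ks, function(k) {
    (2 * sum(P[, k] * G[, k]) + eps) / (sum(P[, k]) + sum(G[, k]) + eps)
  }, 0)
  1 - mean(sdk)
}

# Loss plus gradient w.r.t. the head logits, used by the trainer: dL/dp via
# the quotient rule per class, then through the row softmax.
softDiceLossGrad <- function(P, G, eps = 1e-5) {
  K <- ncol(P)
  num <- den <- numeric(K)
  for (k in seq_len(K)) {
    num[k] <- 2 * sum(P[, k] * G[, k]) + eps
    den[k] <- sum(P[, k]) + sum(G[, k]) + eps
  }
  loss <- 1 - mean(num / den)
  dP <- matrix(0, nrow(P), K)
  for (k in seq_len(K))
    dP[, k] <- -(2 * G[, k] / den[k] - num[k] / den[k]^2) / K
  rs <- rowSums(dP * P)
  dLogits <- P * (dP - rs)
  list(loss = loss, dLogits = dLogits)
}

#' Per-case region metrics
#'
#' Computes Dice, sensitivity, specificity and HD95 for the three evaluation
#' regions of one predicted/reference label-map pair.
#'
#' @param predLabels,gtLabels integer arrays with values in \{0, 1, 2, 4\},
#'   identical shape.
#' @param spacing voxel spacing in mm.
#' @param mode region composition mode, see [regionMasks()].
#' @param caseId identifier copied into the output.
#' @return A data.frame with one row per region (ET, WT, TC) and columns
#'   \code{case_id}, \code{region}, \code{dice}, \code{sensitivity},
#'   \code{specificity}, \code{hd95}; undefined values are \code{NA}.
#' @export
evaluatePair <- function(predLabels, gtLabels, spacing = c(1, 1, 1),
                         mode = "standard", caseId = "case") {
  checkPair(predLabels, gtLabels)
  mp <- regionMasks(predLabels, mode)
  mg <- regionMasks(gtLabels, mode)
  rows <- lapply(c("ET", "WT", "TC"), function(r) {
    ss <- sensitivitySpecificity(mp[[r]], mg[[r]])
    data.frame(case_id = caseId, region = r,
               dice = diceCoefficient(mp[[r]], mg[[r]]),
               sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]],
               hd95 = hausdorff95(mp[[r]], mg[[r]], spacing))
  })
  do.call(rbind, rows)
}
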