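# End-to-end inference and evaluation: normalize -> patch -> forward ->
# stitch -> argmax -> label map, and batch evaluation to the challenge's CSV
# reporting layout.

#' Predict the label map of one case
#'
#' Normalizes the case, tiles it with the model's patch shape, runs the
#' forward pass per patch, stitches the per-class probabilities (mean over
#' overlapping patches, renormalized) and takes the per-voxel argmax.  The
#' output has the input volume's shape and values in \{0, 1, 2, 4\}.
#'
#' @param model a \linkS4class{VNetModel}.
#' @param vol a \linkS4class{MultiModalVolume}.
#' @param stride patch stride; default half the patch shape.
#' @param maskPolicy normalization policy, see [zscoreNormalize()].
#' @param returnProbs also return the stitched probability volume.
#' @return Integer label array in the case's native (X, Y, Z) order; if
#'   \code{returnProbs}, a list with \code{labels} and \code{probs} (internal
#'   (D, W, H, class) order).
#' @export
predictCase <- function(model, vol, stride = NULL,
                        maskPolicy = "whole_volume", returnProbs = FALSE) {
  cfg <- model@cfg
  if (is.null(stride)) stride <- pmax(cfg@inputShape %/% 2L, 1L)
  nv <- normalizeCase(vol, maskPolicy)
  x <- inputTensor(nv)
  grid <- buildPatchGrid(dim(x)[1:3], cfg@inputShape, stride)
  probs <- stitchPatches(function(i) vnetForward(model, cropAt(x, grid, i)),
                         grid, cfg@nClasses)
  labels <- fromInternal(probsToLabels(probs))
  if (returnProbs) list(labels = labels, probs = probs) else labels
}

#' @rdname predictCase
#' @param caseDir case directory readable by [loadCase()].
#' @param outFile output NIfTI path; the prediction is written aligned to the
#'   case's FLAIR header.
#' @export
predictCaseToFile <- function(model, caseDir, outFile, stride = NULL,
                              maskPolicy = "whole_volume") {
  vol <- loadCase(caseDir)
  labels <- predictCase(model, vol, stride = stride, maskPolicy = maskPolicy)
  files <- list.files(caseDir, full.names = TRUE)
  ref <- files[grepl("_flair\\.nii(\\.gz)?$", basename(files))][1]
  template <- RNifti::readNifti(ref)
  img <- RNifti::asNifti(array(as.integer(labels), dim(labels)),
                         reference = template)
  RNifti::writeNifti(img, outFile, datatype = "int16")
  invisible(outFile)
}

#' Evaluate predictions against reference segmentations
#'
#' Matches prediction and truth label maps by case id, computes the per-case,
#' per-region metrics with [evaluatePair()], and summarizes them.  Undefined
#' metrics (empty regions) stay \code{NA} in the per-case table and are
#' counted separately in the summary rather than imputed.
#'
#' @param pred named list of predicted label arrays, or a directory of
#'   predicted NIfTI files named \code{<case_id>.nii[.gz]}.
#' @param truth named list of reference label arrays, or a directory of cases
#'   readable by [loadCase()].
#' @param spacing voxel spacing in mm.
#' @param mode region composition, see [regionMasks()].
#' @param csvFile optional path; the per-case table is written as CSV.
#' @return A list: \code{perCase} (data.frame: case_id, region, dice,
#'   sensitivity, specificity, hd95) and \code{summary} (per region: mean and
#'   median of each defined metric, number of cases, number undefined).
#' @export
evaluateCases <- function(pred, truth, spacing = c(1, 1, 1),
                          mode = "standard", csvFile = NULL) {
  if (is.character(pred)) {
    files <- list.files(pred, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
    pred <- stats::setNames(lapply(files, function(f) {
      img <- RNifti::readNifti(f)
      array(as.integer(round(img)), dim(img))
    }), ids)
  }
  if (is.character(truth)) {
    dirs <- list.dirs(truth, recursive = FALSE)
    truth <- stats::setNames(lapply(dirs, function(d) labelVolume(loadCase(d))),
                             basename(dirs))
  }
  if (is.null(names(pred)) || is.null(names(truth)))
    missingPairError("pred and truth must be named by case id")
  unmatched <- setdiff(names(pred), names(truth))
  if (length(unmatched))
    missingPairError("no reference for case(s): %s",
                     paste(unmatched, collapse = ", "))
  perCase <- do.call(rbind, lapply(names(pred), function(id) {
    evaluatePair(pred[[id]], truth[[id]], spacing = spacing, mode = mode,
                 caseId = id)
  }))
  summ <- do.call(rbind, lapply(split(perCase, perCase$region), function(df) {
    data.frame(
      region = df$region[1], n = nrow(df),
      dice_mean = mean(df$dice, na.rm = TRUE),
      dice_median = median(df$dice, na.rm = TRUE),
      sensitivity_mean = mean(df$sensitivity, na.rm = TRUE),
      specificity_mean = mean(df$specificity, na.rm = TRUE),
      hd95_mean = mean(df$hd95, na.rm = TRUE),
      n_undefined_dice = sum(is.na(df$dice)),
      n_undefined_hd95 = sum(is.na(df$hd95))
    )
  }))
  rownames(summ) <- NULL
  if (!is.null(csvFile)) write.csv(perCase, csvFile, row.names = FALSE)
  list(perCase = perCase, summary = summ)
}
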