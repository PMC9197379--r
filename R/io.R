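#' Read a multi-modal case from a directory of NIfTI files
#'
#' Locates the four modality files (and an optional segmentation) by filename
#' suffix, reads them with \pkg{RNifti}, checks that all modalities share one
#' shape, and coerces labels to integers in \{0, 1, 2, 4\}.
#'
#' @param caseDir directory holding one case's NIfTI files.
#' @param suffixes named character vector mapping the roles
#'   \code{flair}, \code{t1}, \code{t1ce}, \code{t2}, \code{seg} to filename
#'   suffixes (before \code{.nii}/\code{.nii.gz}).
#' @return A \linkS4class{MultiModalVolume}; its \code{caseId} is the
#'   directory basename.
#' @seealso [saveCase()], [generateDataset()]
#' @export
loadCase <- function(caseDir,
                     suffixes = c(flair = "_flair", t1 = "_t1",
                                  t1ce = "_t1ce", t2 = "_t2", seg = "_seg")) {
  if (!dir.exists(caseDir)) vnetStop("IOError", "no such directory: %s", caseDir)
  files <- list.files(caseDir, full.names = TRUE)
  findFile <- function(suffix) {
    hit <- files[grepl(paste0(suffix, "\\.nii(\\.gz)?$"), basename(files))]
    if (length(hit)) hit[[1]] else NULL
  }
  vols <- list()
  for (m in c("flair", "t1", "t1ce", "t2")) {
    f <- findFile(suffixes[[m]])
    if (is.null(f)) missingModalityError(m)
    vols[[m]] <- RNifti::readNifti(f)
  }
  d <- dim(vols$flair)
  for (m in c("t1", "t1ce", "t2"))
    if (!identical(dim(vols[[m]]), d))
      shapeMismatchError("modality '%s' shape (%s) differs from flair (%s)",
                         m, paste(dim(vols[[m]]), collapse = "x"),
                         paste(d, collapse = "x"))
  spacing <- RNifti::pixdim(vols$flair)[1:3]
  labels <- NULL
  segFile <- findFile(suffixes[["seg"]])
  if (!is.null(segFile)) {
    seg <- RNifti::readNifti(segFile)
    if (!identical(dim(seg), d))
      shapeMismatchError("segmentation shape differs from modalities")
    labels <- array(as.integer(round(seg)), dim = d)
    bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L, 4L))
    if (length(bad))
      labelDomainError("label values outside {0,1,2,4}: %s",
                       paste(bad, collapse = ", "))
  }
  MultiModalVolume(
    flair = array(as.numeric(vols$flair), d),
    t1 = array(as.numeric(vols$t1), d),
    t1ce = array(as.numeric(vols$t1ce), d),
    t2 = array(as.numeric(vols$t2), d),
    labels = labels, caseId = basename(normalizePath(caseDir)),
    spacing = as.numeric(spacing)
  )
}

#' Write a multi-modal case as NIfTI files
#'
#' Inverse of [loadCase()]: writes the four modalities (and labels, when
#' present) under the case's id with the standard suffix convention.
#'
#' @param vol a \linkS4class{MultiModalVolume}.
#' @param dir output directory (created if needed); files are written directly
#'   into it.
#' @param compress write \code{.nii.gz} (default) or plain \code{.nii}.
#' @return The directory path, invisibly.
#' @export
saveCase <- function(vol, dir, compress = TRUE) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    vnetStop("IOError", "cannot create directory: %s", dir)
  ext <- if (compress) ".nii.gz" else ".nii"
  writeOne <- function(arr, suffix, datatype) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- voxelSpacing(vol)
    RNifti::writeNifti(img, file.path(dir, paste0(caseId(vol), suffix, ext)),
                       datatype = datatype)
  }
  writeOne(modality(vol, "flair"), "_flair", "float")
  writeOne(modality(vol, "t1"),    "_t1",    "float")
  writeOne(modality(vol, "t1ce"),  "_t1ce",  "float")
  writeOne(modality(vol, "t2"),    "_t2",    "float")
  if (hasLabels(vol)) writeOne(labelVolume(vol), "_seg", "int16")
  invisible(dir)
}

#' Cache a patch tensor as a raw binary array with a JSON sidecar
#'
#' Preprocessed patches can be cached on disk as little-endian doubles plus a
#' JSON sidecar recording the case id, 0-based origin and array dimensions,
#' so later training runs skip normalization and extraction.
#'
#' @param tensor numeric array (depth, width, height, channel).
#' @param path output path for the binary payload; the sidecar is
#'   \code{<path>.json}.
#' @param caseId,origin,gridMeta metadata stored in the sidecar.
#' @return \code{path}, invisibly.
#' @export
writePatchCache <- function(tensor, path, caseId = "case",
                            origin = c(0L, 0L, 0L), gridMeta = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(tensor), con, size = 8, endian = "little")
  meta <- list(case_id = caseId, origin = as.integer(origin),
               dim = as.integer(dim(tensor)), grid = gridMeta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePatchCache
#' @return For \code{readPatchCache}, a list with elements \code{tensor},
#'   \code{caseId}, \code{origin} and \code{grid}.
#' @export
readPatchCache <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  list(tensor = array(x, dim = meta$dim), caseId = meta$case_id,
       origin = as.integer(meta$origin), grid = meta$grid)
}
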