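#' MultiModalVolume: one multi-modal MRI case
#'
#' Container for a single BraTS-style case: four co-registered, skull-stripped
#' modality volumes (FLAIR, T1, T1ce, T2) stored in native NIfTI axis order
#' (X, Y, Z), an optional integer label volume with values in \{0, 1, 2, 4\},
#' and the voxel spacing in millimetres.
#'
#' @slot flair,t1,t1ce,t2 numeric 3-D arrays, identical dimensions.
#' @slot labels integer 3-D array of the same dimensions, or \code{NULL}.
#' @slot caseId character scalar identifying the case.
#' @slot spacing numeric length-3 voxel spacing (mm).
#'
#' @export
setClass("MultiModalVolume",
  representation(
    flair = "array", t1 = "array", t1ce = "array", t2 = "array",
    labels = "ANY", caseId = "character", spacing = "numeric"
  )
)

setValidity("MultiModalVolume", function(object) {
  d <- dim(object@flair)
  if (length(d) != 3L) return("modality volumes must be 3-D arrays")
  for (m in c("t1", "t1ce", "t2"))
    if (!identical(dim(slot(object, m)), d))
      return(sprintf("modality '%s' shape differs from flair", m))
  if (!is.null(object@labels)) {
    if (!identical(dim(object@labels), d))
      return("label volume shape differs from modalities")
    bad <- setdiff(unique(as.integer(object@labels)), c(0L, 1L, 2L, 4L))
    if (length(bad))
      return(sprintf("label values outside {0,1,2,4}: %s",
                     paste(bad, collapse = ", ")))
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values")
  TRUE
})

#' Construct a MultiModalVolume
#'
#' @param flair,t1,t1ce,t2 numeric 3-D arrays of identical shape (X, Y, Z).
#' @param labels optional integer 3-D array, values in \{0, 1, 2, 4\}.
#' @param caseId case identifier.
#' @param spacing voxel spacing in mm (length 3).
#' @return A \linkS4class{MultiModalVolume}.
#' @examples
#' v <- generatePhantom(tinyPhantomSpec())
#' dim(modality(v, "flair"))
#' @export
MultiModalVolume <- function(flair, t1, t1ce, t2, labels = NULL,
                             caseId = "case", spacing = c(1, 1, 1)) {
  d <- dim(flair)
  mods <- list(t1 = t1, t1ce = t1ce, t2 = t2)
  for (m in names(mods))
    if (!identical(dim(mods[[m]]), d))
      shapeMismatchError("modality '%s' shape (%s) differs from flair (%s)",
                         m, paste(dim(mods[[m]]), collapse = "x"),
                         paste(d, collapse = "x"))
  if (!is.null(labels)) {
    if (!identical(dim(labels), d))
      shapeMismatchError("label shape differs from modalities")
    labels <- array(as.integer(round(labels)), dim = d)
    bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L, 4L))
    if (length(bad))
      labelDomainError("label values outside {0,1,2,4}: %s",
                       paste(bad, collapse = ", "))
  }
  new("MultiModalVolume", flair = flair, t1 = t1, t1ce = t1ce, t2 = t2,
      labels = labels, caseId = caseId, spacing = as.numeric(spacing))
}

#' @describeIn MultiModalVolume extract one modality array by name.
#' @param x a \code{MultiModalVolume}.
#' @param name one of \code{"flair"}, \code{"t1"}, \code{"t1ce"}, \code{"t2"}.
#' @export
modality <- function(x, name = c("flair", "t1", "t1ce", "t2")) {
  name <- match.arg(name)
  slot(x, name)
}

#' @describeIn MultiModalVolume the label volume (or \code{NULL}).
#' @export
labelVolume <- function(x) x@labels

#' @describeIn MultiModalVolume whether a label volume is present.
#' @export
hasLabels <- function(x) !is.null(x@labels)

#' @describeIn MultiModalVolume the case identifier.
#' @export
caseId <- function(x) x@caseId

#' @describeIn MultiModalVolume the voxel spacing in mm.
#' @export
voxelSpacing <- function(x) x@spacing

#' @export
setMethod("dim", "MultiModalVolume", function(x) dim(x@flair))

setMethod("show", "MultiModalVolume", function(object) {
  d <- dim(object@flair)
  cat(sprintf("MultiModalVolume '%s': %d x %d x %d voxels, spacing %s mm\n",
              object@caseId, d[1], d[2], d[3],
              paste(object@spacing, collapse = "x")))
  if (hasLabels(object)) {
    tb <- table(factor(object@labels, levels = c(0, 1, 2, 4)))
    cat("  labels:", paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                           collapse = " "), "\n")
  } else cat("  labels: none\n")
})

#' PatchGrid: deterministic tiling of a volume
#'
#' The ordered set of patch origins covering a volume, shared by patch
#' extraction and probability stitching.  Origins are 0-based voxel start
#' coordinates in internal tensor order (depth, width, height); per axis they
#' are the stride multiples within range plus, when needed, a clamped tail
#' origin so every voxel is covered.
#'
#' @slot patchShape,stride integer length-3 (depth, width, height).
#' @slot origins integer matrix, one row per patch, 0-based (d, w, h).
#' @slot volumeShape integer length-3 volume extents (depth, width, height).
#'
#' @export
setClass("PatchGrid",
  representation(patchShape = "integer", stride = "integer",
                 origins = "matrix", volumeShape = "integer")
)

setValidity("PatchGrid", function(object) {
  if (any(object@patchShape < 1L) || any(object@stride < 1L))
    return("patchShape and stride must be positive")
  ends <- sweep(object@origins, 2, object@patchShape, "+")
  if (any(sweep(ends, 2, object@volumeShape, ">")))
    return("an origin places its patch outside the volume")
  if (any(object@origins < 0L)) return("origins must be non-negative")
  TRUE
})

#' @describeIn PatchGrid the 0-based origin matrix (one row per patch).
#' @param x a \code{PatchGrid}.
#' @export
origins <- function(x) x@origins

#' @describeIn PatchGrid number of patches in the grid.
#' @export
nPatches <- function(x) nrow(x@origins)

#' @describeIn PatchGrid the patch extents (depth, width, height).
#' @export
patchShape <- function(x) x@patchShape

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patches of %s, stride %s, over volume %s\n",
              nrow(object@origins),
              paste(object@patchShape, collapse = "x"),
              paste(object@stride, collapse = "x"),
              paste(object@volumeShape, collapse = "x")))
})
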