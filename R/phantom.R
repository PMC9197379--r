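# Synthetic BraTS-shaped phantom cases: a brain ellipsoid containing three
# nested tumor ellipsoids (edema > core > enhancing), four modality volumes
# with class-dependent mean intensities plus Gaussian noise, and the matching
# {0, 1, 2, 4} label map.  The phantoms make every other module testable
# without downloading any data.

#' PhantomSpec: parameters of one synthetic case
#'
#' @slot shape integer (X, Y, Z) voxel extents.
#' @slot brainRadiusFrac brain ellipsoid semi-axes as a fraction of the half
#'   extents.
#' @slot tumorCenter numeric voxel triple.
#' @slot regionRadii list of three decreasing semi-axis triples:
#'   \code{edema}, \code{core}, \code{enhancing}.
#' @slot intensityTable numeric matrix, modalities (flair, t1, t1ce, t2) by
#'   tissue classes (background, brain, edema, core, enhancing): mean
#'   intensity of each class in each modality.
#' @slot noiseSigma Gaussian noise standard deviation (intensity units).
#' @slot spacing voxel spacing in mm.
#' @slot seed RNG seed; the phantom is a pure function of the spec.
#' @slot caseId character id.
#'
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", brainRadiusFrac = "numeric",
                 tumorCenter = "numeric", regionRadii = "list",
                 intensityTable = "matrix", noiseSigma = "numeric",
                 spacing = "numeric", seed = "integer", caseId = "character")
)

setValidity("PhantomSpec", function(object) {
  rr <- object@regionRadii
  if (!all(c("edema", "core", "enhancing") %in% names(rr)))
    return("regionRadii needs elements edema, core, enhancing")
  if (!all(rr$enhancing < rr$core) || !all(rr$core < rr$edema))
    return("region radii must strictly decrease: edema > core > enhancing")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (!identical(rownames(object@intensityTable),
                 c("flair", "t1", "t1ce", "t2")) ||
      !identical(colnames(object@intensityTable),
                 c("background", "brain", "edema", "core", "enhancing")))
    return("intensityTable must be modalities x tissue classes")
  TRUE
})

# Stylised contrast: FLAIR and T2 bright in edema, T1ce bright in enhancing
# tumor, T1 hypointense in tumor tissue -- enough contrast that each region
# is identifiable from the channel combination, as in real BraTS cases.
defaultIntensityTable <- function() {
  m <- rbind(
    flair = c(0, 100, 160, 130, 140),
    t1    = c(0, 120,  90,  70, 110),
    t1ce  = c(0, 110,  95,  80, 190),
    t2    = c(0, 100, 150, 140, 120)
  )
  colnames(m) <- c("background", "brain", "edema", "core", "enhancing")
  m
}

#' Construct a phantom specification
#'
#' @param shape (X, Y, Z) voxel extents; default the BraTS 240 x 240 x 155.
#' @param brainRadiusFrac brain semi-axes as a fraction of the half extents.
#' @param tumorCenter voxel triple; default offset from the brain centre.
#' @param regionRadii list with decreasing semi-axis triples \code{edema},
#'   \code{core}, \code{enhancing}.
#' @param intensityTable modality-by-class mean intensities; see
#'   \code{defaultIntensityTable} in the package source for the default
#'   contrast.
#' @param noiseSigma additive Gaussian noise sd; default 5 on a ~100
#'   intensity scale.
#' @param spacing voxel spacing (mm); default 1 mm isotropic.
#' @param seed RNG seed.
#' @param caseId case identifier.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(240L, 240L, 155L), brainRadiusFrac = 0.8,
                        tumorCenter = NULL,
                        regionRadii = list(edema = c(40, 36, 30),
                                           core = c(25, 22, 18),
                                           enhancing = c(12, 11, 9)),
                        intensityTable = defaultIntensityTable(),
                        noiseSigma = 5, spacing = c(1, 1, 1), seed = 1L,
                        caseId = "phantom") {
  shape <- as.integer(shape)
  if (is.null(tumorCenter)) tumorCenter <- shape / 2 + shape / 10
  spec <- new("PhantomSpec", shape = shape,
              brainRadiusFrac = brainRadiusFrac,
              tumorCenter = as.numeric(tumorCenter), regionRadii = regionRadii,
              intensityTable = intensityTable, noiseSigma = noiseSigma,
              spacing = as.numeric(spacing), seed = as.integer(seed),
              caseId = caseId)
  checkTumorInsideBrain(spec)
  spec
}

#' @rdname phantomSpec
#' @details \code{tinyPhantomSpec} is the desk-scale preset (32 x 32 x 24
#'   voxels) used with [tinyNetworkConfig()] and 16^3 patches, sized so that
#'   an overfit training run completes on one CPU in minutes.
#' @export
tinyPhantomSpec <- function(seed = 1L, caseId = "tiny-phantom",
                            noiseSigma = 5) {
  phantomSpec(shape = c(32L, 32L, 24L), brainRadiusFrac = 0.85,
              tumorCenter = c(18, 17, 13),
              regionRadii = list(edema = c(9, 8, 7), core = c(6, 5.5, 4.5),
                                 enhancing = c(3, 3, 2.5)),
              noiseSigma = noiseSigma, seed = seed, caseId = caseId)
}

checkTumorInsideBrain <- function(spec) {
  bc <- spec@shape / 2
  br <- spec@brainRadiusFrac * spec@shape / 2
  # conservative bounding check: tumor bounding box inside the brain box
  off <- abs(spec@tumorCenter - bc) + spec@regionRadii$edema
  if (any(off > br))
    configError("tumor (centre %s, edema radii %s) extends outside the brain ellipsoid",
                paste(round(spec@tumorCenter), collapse = ","),
                paste(spec@regionRadii$edema, collapse = ","))
  invisible(TRUE)
}

# Squared normalized ellipsoid coordinate of every voxel: <= 1 means inside.
ellipsoidField <- function(shape, center, radii) {
  x2 <- ((seq_len(shape[1]) - center[1]) / radii[1])^2
  y2 <- ((seq_len(shape[2]) - center[2]) / radii[2])^2
  z2 <- ((seq_len(shape[3]) - center[3]) / radii[3])^2
  outer(outer(x2, y2, "+"), z2, "+")
}

#' Generate a synthetic multi-modal phantom case
#'
#' Builds the label map first — 0 outside the tumor, 2 in the edema shell,
#' 1 in the core shell, 4 in the enhancing centre, so that under the standard
#' region composition the regions are nested (ET within TC within WT) — then
#' fills each modality with its class mean intensity plus independent
#' zero-mean Gaussian noise.  Voxels outside the brain ellipsoid are exactly
#' zero in every modality, emulating skull-stripped data.  The result is a
#' pure function of the spec (seeded RNG).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{MultiModalVolume} with labels.
#' @examples
#' v <- generatePhantom(tinyPhantomSpec())
#' table(labelVolume(v))
#' @export
generatePhantom <- function(spec) {
  checkTumorInsideBrain(spec)
  shape <- spec@shape
  bc <- shape / 2
  br <- spec@brainRadiusFrac * shape / 2
  brain <- ellipsoidField(shape, bc, br) <= 1
  inEdema <- ellipsoidField(shape, spec@tumorCenter, spec@regionRadii$edema) <= 1
  inCore <- ellipsoidField(shape, spec@tumorCenter, spec@regionRadii$core) <= 1
  inEnh <- ellipsoidField(shape, spec@tumorCenter, spec@regionRadii$enhancing) <= 1
  labels <- array(0L, shape)
  labels[inEdema] <- 2L
  labels[inCore] <- 1L
  labels[inEnh] <- 4L
  # tissue class index per voxel: 1 background, 2 brain, 3 edema, 4 core, 5 enhancing
  cls <- array(1L, shape)
  cls[brain] <- 2L
  cls[inEdema] <- 3L
  cls[inCore] <- 4L
  cls[inEnh] <- 5L
  withSeed(spec@seed, {
    mkMod <- function(modality) {
      v <- array(spec@intensityTable[modality, ][cls], shape)
      if (spec@noiseSigma > 0) {
        noise <- array(rnorm(prod(shape), 0, spec@noiseSigma), shape)
        v[brain] <- v[brain] + noise[brain] # background stays exactly 0
      }
      v
    }
    MultiModalVolume(flair = mkMod("flair"), t1 = mkMod("t1"),
                     t1ce = mkMod("t1ce"), t2 = mkMod("t2"),
                     labels = labels, caseId = spec@caseId,
                     spacing = spec@spacing)
  })
}

#' Generate a dataset of jittered phantom cases on disk
#'
#' Writes \code{n} NIfTI cases derived from a base spec, with tumor centre,
#' region radii and class intensities independently jittered per case, plus a
#' JSON manifest recording each case's effective parameters and per-file
#' checksums.  Every written case round-trips through [loadCase()].
#'
#' @param n number of cases.
#' @param dir output directory; one subdirectory per case.
#' @param baseSpec the \linkS4class{PhantomSpec} to jitter (default tiny
#'   preset).
#' @param jitter list with \code{center} (voxels, additive uniform),
#'   \code{radiiFrac} and \code{intensityFrac} (multiplicative uniform
#'   half-widths).
#' @param seed master seed; case i derives seed \code{seed * 1000 + i}.
#' @param compress write .nii.gz (default) or .nii.
#' @return Invisibly, the manifest as a list.
#' @export
generateDataset <- function(n, dir, baseSpec = tinyPhantomSpec(),
                            jitter = list(center = 1.5, radiiFrac = 0.1,
                                          intensityFrac = 0.05),
                            seed = 1L, compress = TRUE) {
  if (n < 1) configError("need n >= 1 cases")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    vnetStop("IOError", "cannot create directory: %s", dir)
  manifest <- list()
  for (i in seq_len(n)) {
    caseSeed <- baseSpec@seed + seed * 1000L + i
    spec <- withSeed(caseSeed, {
      rr <- lapply(baseSpec@regionRadii, function(r)
        r * runif(3, 1 - jitter$radiiFrac, 1 + jitter$radiiFrac))
      # keep strict nesting after jitter
      rr$core <- pmin(rr$core, rr$edema * 0.8)
      rr$enhancing <- pmin(rr$enhancing, rr$core * 0.8)
      it <- baseSpec@intensityTable *
        matrix(runif(length(baseSpec@intensityTable),
                     1 - jitter$intensityFrac, 1 + jitter$intensityFrac),
               nrow(baseSpec@intensityTable))
      dimnames(it) <- dimnames(baseSpec@intensityTable)
      phantomSpec(shape = baseSpec@shape,
                  brainRadiusFrac = baseSpec@brainRadiusFrac,
                  tumorCenter = baseSpec@tumorCenter +
                    runif(3, -jitter$center, jitter$center),
                  regionRadii = rr, intensityTable = it,
                  noiseSigma = baseSpec@noiseSigma,
                  spacing = baseSpec@spacing, seed = caseSeed,
                  caseId = sprintf("case%03d", i))
    })
    vol <- generatePhantom(spec)
    caseDir <- file.path(dir, caseId(vol))
    saveCase(vol, caseDir, compress = compress)
    sums <- tools::md5sum(list.files(caseDir, full.names = TRUE))
    names(sums) <- basename(names(sums))
    manifest[[caseId(vol)]] <- list(
      case_id = caseId(vol), seed = caseSeed,
      shape = spec@shape, tumor_center = round(spec@tumorCenter, 3),
      region_radii = lapply(spec@regionRadii, function(r) round(r, 3)),
      noise_sigma = spec@noiseSigma, checksums = as.list(sums))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
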