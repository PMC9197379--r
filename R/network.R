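#' VNetConfig: architecture configuration
#'
#' Describes the V-Net encoder/decoder: per-encoder-stage filter counts (the
#' chain must double stage to stage), the patch input shape, class count,
#' scSE reduction ratio, skip-fusion mode, and the non-local block's residual
#' flag.  The default configuration reproduces the published 10-layer
#' architecture: a 20-filter stem, encoder stages at 20/40/80/160/320 filters
#' over five resolutions with strided-convolution downsampling, a non-local
#' bottleneck, and a four-stage decoder with transposed-convolution
#' upsampling, additive skip fusion and a 1x1x1 softmax head over four
#' classes.
#'
#' @slot inputShape integer (depth, width, height) of one model input patch.
#' @slot inChannels input channels (4 modalities).
#' @slot filters integer vector, filters per encoder stage.
#' @slot nClasses output classes.
#' @slot scseReduction cSE reduction ratio r.
#' @slot skipFusion \code{"add"} or \code{"concat"}.
#' @slot nonlocalResidual logical; add the input back inside the non-local
#'   block.
#' @slot seed integer seed for weight initialization.
#'
#' @export
setClass("VNetConfig",
  representation(inputShape = "integer", inChannels = "integer",
                 filters = "integer", nClasses = "integer",
                 scseReduction = "integer", skipFusion = "character",
                 nonlocalResidual = "logical", seed = "integer")
)

#' Construct a network configuration
#'
#' @param inputShape patch shape (depth, width, height); default
#'   \code{c(64, 128, 128)}.
#' @param inChannels input channel count; default 4.
#' @param filters filters per encoder stage; default
#'   \code{c(20, 40, 80, 160, 320)}.  Must double at every stage.
#' @param nClasses output classes; default 4.
#' @param scseReduction cSE reduction ratio; default 4.
#' @param skipFusion \code{"add"} (default; matches the published stage
#'   shapes) or \code{"concat"}.
#' @param nonlocalResidual default \code{FALSE}.
#' @param seed weight-initialization seed.
#' @return A \linkS4class{VNetConfig}.
#' @export
networkConfig <- function(inputShape = c(64L, 128L, 128L), inChannels = 4L,
                          filters = c(20L, 40L, 80L, 160L, 320L),
                          nClasses = 4L, scseReduction = 4L,
                          skipFusion = c("add", "concat"),
                          nonlocalResidual = FALSE, seed = 42L) {
  skipFusion <- match.arg(skipFusion)
  cfg <- new("VNetConfig", inputShape = as.integer(inputShape),
             inChannels = as.integer(inChannels),
             filters = as.integer(filters), nClasses = as.integer(nClasses),
             scseReduction = as.integer(scseReduction),
             skipFusion = skipFusion,
             nonlocalResidual = isTRUE(nonlocalResidual),
             seed = as.integer(seed))
  validateConfig(cfg)
  cfg
}

#' @rdname networkConfig
#' @export
defaultNetworkConfig <- function(seed = 42L) networkConfig(seed = seed)

#' @rdname networkConfig
#' @details \code{tinyNetworkConfig} is a desk-scale preset (16x16x16 input
#'   patches, 8..128 filters, reduction 4) small enough to train on one CPU
#'   in minutes; it is the configuration used with the tiny phantom preset.
#' @export
tinyNetworkConfig <- function(seed = 42L)
  networkConfig(inputShape = c(16L, 16L, 16L),
                filters = c(8L, 16L, 32L, 64L, 128L), seed = seed)

validateConfig <- function(cfg) {
  n <- length(cfg@filters)
  if (n < 2L) configError("need at least 2 encoder stages")
  for (i in seq_len(n - 1L))
    if (cfg@filters[i + 1L] != 2L * cfg@filters[i])
      configError("stage %d: filters must double along the encoder (%d -> %d)",
                  i + 1L, cfg@filters[i], cfg@filters[i + 1L])
  down <- 2L^(n - 1L)
  if (any(cfg@inputShape %% down != 0L))
    configError("input shape %s not divisible by 2^%d",
                paste(cfg@inputShape, collapse = "x"), n - 1L)
  if (cfg@filters[1] %% cfg@scseReduction != 0L)
    configError("stage 1: filters (%d) not divisible by scSE reduction r=%d",
                cfg@filters[1], cfg@scseReduction)
  if (cfg@filters[n] %% 2L != 0L)
    configError("stage %d: bottleneck filters must be even for the non-local block", n)
  invisible(TRUE)
}

nStages <- function(cfg) length(cfg@filters)

#' Symbolic shape trace of the network
#'
#' Propagates the feature-map shape through every model layer without
#' allocating weights.  Rows list each layer's input shape
#' (D, W, H, C): the stem (layer 0), the encoder stages, and the decoder
#' stages.  For the default configuration the 10 rows reproduce the published
#' architecture table.
#'
#' @param cfg a \linkS4class{VNetConfig}.
#' @return A data.frame with columns \code{layer}, \code{path}, \code{D},
#'   \code{W}, \code{H}, \code{C}.
#' @examples
#' shapeTrace(defaultNetworkConfig())
#' @export
shapeTrace <- function(cfg) {
  validateConfig(cfg)
  n <- nStages(cfg)
  rows <- list()
  sp <- cfg@inputShape
  rows[[1]] <- data.frame(layer = 0L, path = "stem",
                          D = sp[1], W = sp[2], H = sp[3], C = cfg@inChannels)
  for (s in seq_len(n)) { # encoder stage s sees resolution sp / 2^(s-1)
    r <- sp %/% (2L^(s - 1L))
    rows[[length(rows) + 1L]] <-
      data.frame(layer = s, path = if (s == n) "bottleneck" else "encoder",
                 D = r[1], W = r[2], H = r[3], C = cfg@filters[s])
  }
  for (s in rev(seq_len(n - 1L))) { # decoder stage at resolution of encoder s
    r <- sp %/% (2L^(s - 1L))
    rows[[length(rows) + 1L]] <-
      data.frame(layer = 2L * n - s, path = "decoder",
                 D = r[1], W = r[2], H = r[3],
                 C = cfg@filters[s] * (if (cfg@skipFusion == "concat") 2L else 1L))
  }
  do.call(rbind, rows)
}

#' Layer table of the architecture
#'
#' A human-readable companion to [shapeTrace()]: per layer, the kernel size,
#' filter count, number of convolution layers, whether scSE and non-local
#' blocks are present, the activation, and the input shape.
#'
#' @inheritParams shapeTrace
#' @return A data.frame with one row per model layer.
#' @export
stageTable <- function(cfg) {
  tr <- shapeTrace(cfg)
  n <- nStages(cfg)
  filt <- c(cfg@filters[1],                      # stem
            cfg@filters,                         # encoder stages
            rev(cfg@filters[-n]))                # decoder stages
  nconv <- c(1L, ifelse(seq_len(n) == 1L, 1L, 2L), rep(2L, n - 1L))
  data.frame(
    layer = tr$layer, type = "conv", kernel = "3x3x3",
    filters = filt, convLayers = nconv,
    scse = tr$path != "stem",
    nonlocal = tr$path == "bottleneck",
    activation = "ReLU",
    input = sprintf("%d x %d x %d x %d", tr$D, tr$W, tr$H, tr$C)
  )
}

#' VNetModel: a built network
#'
#' Holds the configuration, the named list of parameter arrays, and a JSON
#' architecture fingerprint used to verify checkpoint/config compatibility.
#'
#' @slot cfg the \linkS4class{VNetConfig}.
#' @slot params named list of numeric matrices/vectors.
#' @slot fingerprint character scalar (JSON).
#'
#' @export
setClass("VNetModel",
  representation(cfg = "VNetConfig", params = "list", fingerprint = "character")
)

setMethod("show", "VNetModel", function(object) {
  np <- sum(vapply(object@params, length, 0L))
  cat(sprintf(
    "VNetModel: %d encoder stages, filters %s, input %s, %d classes\n  %s parameters in %d tensors\n",
    nStages(object@cfg), paste(object@cfg@filters, collapse = "/"),
    paste(object@cfg@inputShape, collapse = "x"), object@cfg@nClasses,
    format(np, big.mark = ","), length(object@params)))
})

#' @describeIn buildNetwork the model's architecture fingerprint (JSON).
#' @param model a \linkS4class{VNetModel}.
#' @export
modelFingerprint <- function(model) model@fingerprint

configFingerprint <- function(cfg) {
  as.character(jsonlite::toJSON(list(
    inputShape = cfg@inputShape, inChannels = cfg@inChannels,
    filters = cfg@filters, nClasses = cfg@nClasses,
    scseReduction = cfg@scseReduction, skipFusion = cfg@skipFusion,
    nonlocalResidual = cfg@nonlocalResidual
  ), auto_unbox = TRUE))
}

convW <- function(cin, cout) matrix(initTruncNormal(27 * cin * cout, 27 * cin),
                                    27 * cin, cout)

#' Build the scSE-NL V-Net
#'
#' Allocates and seeds all trainable parameters for the configured
#' architecture: a stem convolution; encoder stages of 3x3x3 convolutions
#' followed by scSE gating and a residual addition of the stage input, each
#' followed by a stride-2 3x3x3 downsampling convolution (there is no pooling
#' anywhere); a non-local self-attention block after the last (bottleneck)
#' encoder stage; decoder stages of transposed-convolution upsampling, skip
#' fusion with the mirror encoder stage, convolutions, scSE and residual
#' addition; and a 1x1x1 convolution to the class channels followed by a
#' voxelwise softmax.  All activations are ReLU.
#'
#' @param cfg a \linkS4class{VNetConfig}.
#' @return A \linkS4class{VNetModel}.
#' @seealso [vnetForward()], [trainModel()], [shapeTrace()]
#' @export
buildNetwork <- function(cfg) {
  validateConfig(cfg)
  n <- nStages(cfg)
  f <- cfg@filters
  withSeed(cfg@seed, {
    p <- list()
    p[["stem.W"]] <- convW(cfg@inChannels, f[1]); p[["stem.b"]] <- numeric(f[1])
    for (s in seq_len(n)) {
      nconv <- if (s == 1L) 1L else 2L
      for (j in seq_len(nconv)) {
        p[[sprintf("enc%d.conv%d.W", s, j)]] <- convW(f[s], f[s])
        p[[sprintf("enc%d.conv%d.b", s, j)]] <- numeric(f[s])
      }
      wc <- cseWeights(f[s], cfg@scseReduction)
      p[[sprintf("enc%d.cse.W1", s)]] <- wc$W1
      p[[sprintf("enc%d.cse.b1", s)]] <- wc$b1
      p[[sprintf("enc%d.cse.W2", s)]] <- wc$W2
      p[[sprintf("enc%d.cse.b2", s)]] <- wc$b2
      wsse <- sseWeights(f[s])
      p[[sprintf("enc%d.sse.w", s)]] <- wsse$w
      p[[sprintf("enc%d.sse.b", s)]] <- wsse$b
      if (s < n) {
        p[[sprintf("down%d.W", s)]] <- convW(f[s], f[s + 1])
        p[[sprintf("down%d.b", s)]] <- numeric(f[s + 1])
      }
    }
    wnl <- nonlocalWeights(f[n], residual = cfg@nonlocalResidual)
    for (nm in c("Wtheta", "btheta", "Wphi", "bphi", "Wg", "bg", "Wz", "bz"))
      p[[paste0("nl.", nm)]] <- wnl[[nm]]
    for (s in rev(seq_len(n - 1L))) {
      # transposed conv f[s+1] -> f[s]; weights stored as the adjoint conv
      # (27*f[s] x f[s+1]); fan-in is k^3/stride^3 * Cin
      p[[sprintf("up%d.U", s)]] <- matrix(
        initTruncNormal(27 * f[s] * f[s + 1], 27 * f[s + 1] / 8),
        27 * f[s], f[s + 1])
      p[[sprintf("up%d.b", s)]] <- numeric(f[s])
      cin1 <- f[s] * (if (cfg@skipFusion == "concat") 2L else 1L)
      p[[sprintf("dec%d.conv1.W", s)]] <- convW(cin1, f[s])
      p[[sprintf("dec%d.conv1.b", s)]] <- numeric(f[s])
      p[[sprintf("dec%d.conv2.W", s)]] <- convW(f[s], f[s])
      p[[sprintf("dec%d.conv2.b", s)]] <- numeric(f[s])
      wc <- cseWeights(f[s], cfg@scseReduction)
      p[[sprintf("dec%d.cse.W1", s)]] <- wc$W1
      p[[sprintf("dec%d.cse.b1", s)]] <- wc$b1
      p[[sprintf("dec%d.cse.W2", s)]] <- wc$W2
      p[[sprintf("dec%d.cse.b2", s)]] <- wc$b2
      wsse <- sseWeights(f[s])
      p[[sprintf("dec%d.sse.w", s)]] <- wsse$w
      p[[sprintf("dec%d.sse.b", s)]] <- wsse$b
    }
    p[["head.W"]] <- matrix(initTruncNormal(f[1] * cfg@nClasses, f[1]),
                            f[1], cfg@nClasses)
    p[["head.b"]] <- numeric(cfg@nClasses)
    new("VNetModel", cfg = cfg, params = p,
        fingerprint = configFingerprint(cfg))
  })
}
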