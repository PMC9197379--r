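# Training: soft-Dice loss on sampled patches, Adam updates, seeded and
# resumable checkpoints.

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# One optimization step on a single (tensor, labels) patch pair.
trainStep <- function(model, tensor, labels, optState, lr,
                      includeBackground = TRUE) {
  fw <- vnetForwardInternal(model, tensor, keepCache = TRUE)
  d <- dim(fw$probs)
  P <- matrix(fw$probs, prod(d[1:3]), d[4])
  G <- matrix(labelsToOneHot(labels), prod(d[1:3]), d[4])
  lg <- softDiceLossGrad(P, G)
  grads <- vnetBackward(model, fw$cache, lg$dLogits)
  upd <- adamStep(model@params, grads, optState, lr = lr)
  model@params <- upd$params
  list(model = model, optState = upd$state, loss = lg$loss)
}

#' Train the network on phantom or loaded cases
#'
#' Minimizes the soft Dice loss over patches sampled from the training cases.
#' Cases are normalized per modality (Z-score), tiled by a patch grid, and at
#' every step one patch is drawn: with probability \code{foregroundBias} from
#' the patches containing tumor voxels (tumor is rare, so unbiased sampling
#' would mostly show background), otherwise uniformly from the whole grid.
#' With a fixed seed the whole run, including the first-step loss, is
#' reproducible.
#'
#' @param cases a list of \linkS4class{MultiModalVolume} with labels, or a
#'   directory whose subdirectories are cases readable by [loadCase()].
#' @param cfg a \linkS4class{VNetConfig}; the patch shape is
#'   \code{cfg@inputShape}.
#' @param steps number of optimization steps.
#' @param lr Adam learning rate (default 1e-4; the tiny desk-scale preset
#'   trains well at 1e-3).
#' @param stride patch-grid stride; default half the patch shape.
#' @param foregroundBias probability of sampling a tumor-containing patch
#'   (default 0.5).
#' @param maskPolicy normalization policy, see [zscoreNormalize()].
#' @param seed RNG seed for sampling.
#' @param model optionally, a model (and \code{optState}) to resume from; its
#'   fingerprint must match \code{cfg}.
#' @param optState optimizer state when resuming.
#' @param checkpointEvery write a checkpoint every this many steps.
#' @param checkpointPath file path for checkpoints (required when
#'   \code{checkpointEvery} is set).
#' @param verbose print a line every \code{verbose} steps (0 = silent).
#' @return A list: \code{model}, \code{optState}, and \code{log}, a
#'   data.frame with columns \code{step} and \code{loss}.
#' @seealso [predictCase()], [saveCheckpoint()]
#' @export
trainModel <- function(cases, cfg, steps = 300L, lr = 1e-4, stride = NULL,
                       foregroundBias = 0.5,
                       maskPolicy = "whole_volume", seed = 7L,
                       model = NULL, optState = NULL,
                       checkpointEvery = NULL, checkpointPath = NULL,
                       verbose = 0L) {
  if (is.character(cases)) {
    dirs <- list.dirs(cases, recursive = FALSE)
    cases <- lapply(dirs, loadCase)
  }
  if (length(cases) == 0) emptyDatasetError("no training cases found")
  for (v in cases)
    if (!hasLabels(v)) emptyDatasetError("case '%s' has no labels", caseId(v))
  if (is.null(model)) {
    model <- buildNetwork(cfg)
  } else if (!identical(modelFingerprint(model), configFingerprint(cfg))) {
    configError("checkpoint fingerprint does not match the configuration")
  }
  if (is.null(optState)) optState <- adamInit(model@params)
  if (is.null(stride)) stride <- pmax(cfg@inputShape %/% 2L, 1L)

  # precompute normalized tensors, label tensors and per-case patch grids
  prep <- lapply(cases, function(v) {
    nv <- normalizeCase(v, maskPolicy)
    x <- inputTensor(nv)
    lab <- toInternal(labelVolume(v))
    g <- buildPatchGrid(dim(lab), cfg@inputShape, stride)
    fg <- which(vapply(seq_len(nPatches(g)),
                       function(i) any(cropAt(lab, g, i) > 0L), TRUE))
    list(x = x, lab = lab, grid = g, fg = fg)
  })

  log <- data.frame(step = integer(steps), loss = numeric(steps))
  withSeed(seed, {
    for (st in seq_len(steps)) {
      ci <- sample.int(length(prep), 1L)
      pc <- prep[[ci]]
      useFg <- length(pc$fg) > 0 && runif(1) < foregroundBias
      pi <- if (useFg) pc$fg[sample.int(length(pc$fg), 1L)]
            else sample.int(nPatches(pc$grid), 1L)
      res <- trainStep(model, cropAt(pc$x, pc$grid, pi),
                       cropAt(pc$lab, pc$grid, pi), optState, lr)
      model <- res$model
      optState <- res$optState
      log$step[st] <- st
      log$loss[st] <- res$loss
      if (verbose > 0 && st %% verbose == 0)
        message(sprintf("step %d  loss %.4f", st, res$loss))
      if (!is.null(checkpointEvery) && st %% checkpointEvery == 0L)
        saveCheckpoint(model, checkpointPath, optState = optState, step = st)
    }
  })
  list(model = model, optState = optState, log = log)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the parameters, the optimizer state, the step
#' counter, and the JSON architecture fingerprint; loading verifies the
#' fingerprint against the stored configuration, and [trainModel()] refuses
#' to resume from a checkpoint whose fingerprint does not match its config.
#'
#' @param model a \linkS4class{VNetModel}.
#' @param path checkpoint file path (RDS payload plus a readable
#'   \code{<path>.json} fingerprint sidecar).
#' @param optState optimizer state to store (optional).
#' @param step training step counter.
#' @return \code{path}, invisibly.
#' @export
saveCheckpoint <- function(model, path, optState = NULL, step = 0L) {
  saveRDS(list(cfg = model@cfg, params = model@params,
               fingerprint = model@fingerprint, optState = optState,
               step = step), path)
  writeLines(model@fingerprint, paste0(path, ".json"))
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return For \code{loadCheckpoint}, a list with \code{model},
#'   \code{optState} and \code{step}.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$fingerprint, configFingerprint(ck$cfg)))
    configError("checkpoint fingerprint does not match its stored configuration")
  list(model = new("VNetModel", cfg = ck$cfg, params = ck$params,
                   fingerprint = ck$fingerprint),
       optState = ck$optState, step = ck$step)
}
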