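# Forward and backward passes of the V-Net.  The network topology is fixed by
# VNetConfig, so backpropagation is written out explicitly layer by layer
# rather than through a general autodiff graph; every layer forward returns a
# cache consumed by its backward.  Tensors carry no batch axis: one patch per
# call, batches are looped by the trainer (batch size one is the norm for
# 3-D segmentation at this patch size).

convOutDims <- function(dimsIn, stride)
  (dimsIn + 2L - 3L) %/% stride + 1L

convReluForward <- function(x, W, b, stride, activate = TRUE) {
  d <- dim(x)
  col <- cpp_vol2col(x, as.integer(d), 3L, as.integer(stride), 1L)
  pre <- col %*% W
  pre <- sweep(pre, 2, b, "+")
  mask <- NULL
  if (activate) {
    mask <- pre > 0
    pre[!mask] <- 0
  }
  od <- convOutDims(d[1:3], as.integer(stride))
  list(out = array(pre, c(od, ncol(W))),
       cache = list(col = col, mask = mask, dimsIn = as.integer(d),
                    stride = as.integer(stride)))
}

convReluBackward <- function(dY, W, cache) {
  dM <- matrix(dY, nrow = nrow(cache$col))
  if (!is.null(cache$mask)) dM <- dM * cache$mask
  list(dX = cpp_col2vol(dM %*% t(W), cache$dimsIn, 3L, cache$stride, 1L),
       dW = crossprod(cache$col, dM),
       db = colSums(dM))
}

# Transposed convolution (kernel 3, stride 2, output twice the input extents),
# stored as the adjoint strided conv's weight U of shape (27*Cout x Cin).
convTReluForward <- function(x, U, b, outSpatial) {
  d <- dim(x)
  cout <- nrow(U) %/% 27L
  X <- asPositionMatrix(x)
  colBig <- X %*% t(U) # N_small x 27*Cout
  y <- cpp_col2vol(colBig, as.integer(c(outSpatial, cout)), 3L,
                   c(2L, 2L, 2L), 1L)
  ym <- asPositionMatrix(y)
  ym <- sweep(ym, 2, b, "+")
  mask <- ym > 0
  ym[!mask] <- 0
  list(out = array(ym, c(outSpatial, cout)),
       cache = list(X = X, mask = mask, dimsIn = as.integer(d),
                    dimsOut = as.integer(c(outSpatial, cout))))
}

convTReluBackward <- function(dY, U, cache) {
  dM <- matrix(dY, nrow = nrow(cache$mask)) * cache$mask
  dBig <- array(dM, cache$dimsOut)
  colD <- cpp_vol2col(dBig, cache$dimsOut, 3L, c(2L, 2L, 2L), 1L)
  list(dX = array(colD %*% U, cache$dimsIn),
       dU = crossprod(colD, cache$X),
       db = colSums(dM))
}

cseW <- function(p, pre) list(W1 = p[[paste0(pre, ".cse.W1")]],
                              b1 = p[[paste0(pre, ".cse.b1")]],
                              W2 = p[[paste0(pre, ".cse.W2")]],
                              b2 = p[[paste0(pre, ".cse.b2")]])
sseW <- function(p, pre) list(w = p[[paste0(pre, ".sse.w")]],
                              b = p[[paste0(pre, ".sse.b")]])
nlW <- function(p, residual)
  list(Wtheta = p[["nl.Wtheta"]], btheta = p[["nl.btheta"]],
       Wphi = p[["nl.Wphi"]], bphi = p[["nl.bphi"]],
       Wg = p[["nl.Wg"]], bg = p[["nl.bg"]],
       Wz = p[["nl.Wz"]], bz = p[["nl.bz"]], residual = residual)

vnetForwardInternal <- function(model, x, keepCache = FALSE) {
  cfg <- model@cfg
  p <- model@params
  n <- nStages(cfg)
  f <- cfg@filters
  expected <- c(cfg@inputShape, cfg@inChannels)
  if (!identical(as.integer(dim(x)), expected))
    shapeMismatchError("input shape %s, model expects %s",
                       paste(dim(x), collapse = "x"),
                       paste(expected, collapse = "x"))
  cc <- list()
  st <- convReluForward(x, p[["stem.W"]], p[["stem.b"]], c(1L, 1L, 1L))
  cur <- st$out
  cc$stem <- st$cache
  encOut <- vector("list", n)
  cc$enc <- vector("list", n)
  cc$encIn <- vector("list", n)
  for (s in seq_len(n)) {
    t0 <- cur
    cc$encIn[[s]] <- cur
    nconv <- if (s == 1L) 1L else 2L
    convCache <- vector("list", nconv)
    for (j in seq_len(nconv)) {
      cr <- convReluForward(cur, p[[sprintf("enc%d.conv%d.W", s, j)]],
                            p[[sprintf("enc%d.conv%d.b", s, j)]], c(1L, 1L, 1L))
      cur <- cr$out
      convCache[[j]] <- cr$cache
    }
    sc <- scseForwardCache(cur, cseW(p, paste0("enc", s)), sseW(p, paste0("enc", s)))
    cur <- sc$out + t0
    encOut[[s]] <- cur
    stageCache <- list(convs = convCache, scse = sc$cache)
    if (s < n) {
      dn <- convReluForward(cur, p[[sprintf("down%d.W", s)]],
                            p[[sprintf("down%d.b", s)]], c(2L, 2L, 2L))
      cur <- dn$out
      stageCache$down <- dn$cache
    }
    cc$enc[[s]] <- stageCache
  }
  cc$encOut <- encOut
  nl <- nonlocalForwardCache(cur, nlW(p, cfg@nonlocalResidual))
  cur <- nl$out
  cc$nl <- nl$cache
  cc$dec <- vector("list", n - 1L)
  for (s in rev(seq_len(n - 1L))) {
    outSpatial <- dim(encOut[[s]])[1:3]
    up <- convTReluForward(cur, p[[sprintf("up%d.U", s)]],
                           p[[sprintf("up%d.b", s)]], outSpatial)
    if (cfg@skipFusion == "add") {
      t0 <- up$out + encOut[[s]]
      resBase <- t0
    } else {
      dd <- dim(up$out)
      t0 <- array(c(up$out, encOut[[s]]), c(dd[1:3], 2L * dd[4]))
      resBase <- up$out
    }
    cur <- t0
    convCache <- vector("list", 2L)
    for (j in 1:2) {
      cr <- convReluForward(cur, p[[sprintf("dec%d.conv%d.W", s, j)]],
                            p[[sprintf("dec%d.conv%d.b", s, j)]], c(1L, 1L, 1L))
      cur <- cr$out
      convCache[[j]] <- cr$cache
    }
    sc <- scseForwardCache(cur, cseW(p, paste0("dec", s)), sseW(p, paste0("dec", s)))
    cur <- sc$out + resBase
    cc$dec[[s]] <- list(up = up$cache, convs = convCache, scse = sc$cache)
  }
  X <- asPositionMatrix(cur)
  logits <- sweep(X %*% p[["head.W"]], 2, p[["head.b"]], "+")
  probs <- rowSoftmax(logits)
  out <- array(probs, c(dim(cur)[1:3], cfg@nClasses))
  if (!keepCache) return(list(probs = out))
  cc$headX <- X
  cc$lastDims <- dim(cur)
  list(probs = out, cache = cc)
}

#' Forward pass: class probabilities for one or more patches
#'
#' Runs the network in evaluation mode.  The output has the input's spatial
#' shape with one channel per class, and the per-voxel probabilities sum to
#' one (softmax head).  The pass is deterministic given fixed weights.
#'
#' @param model a \linkS4class{VNetModel} from [buildNetwork()].
#' @param x a (D, W, H, C) input tensor matching the configured input shape,
#'   or a list of such tensors.
#' @return A (D, W, H, nClasses) probability array (or a list of them).
#' @export
vnetForward <- function(model, x) {
  if (is.list(x)) return(lapply(x, function(xi) vnetForwardInternal(model, xi)$probs))
  vnetForwardInternal(model, x)$probs
}

# Backward pass: gradient of the scalar loss w.r.t. every parameter, given
# d(loss)/d(logits) at the head.  Returns a named list parallel to params.
vnetBackward <- function(model, cache, dLogits) {
  cfg <- model@cfg
  p <- model@params
  n <- nStages(cfg)
  g <- list()
  addG <- function(name, val) {
    g[[name]] <<- if (is.null(g[[name]])) val else g[[name]] + val
  }
  # head
  addG("head.W", crossprod(cache$headX, dLogits))
  addG("head.b", colSums(dLogits))
  dCur <- array(dLogits %*% t(p[["head.W"]]), cache$lastDims)
  dEnc <- vector("list", n) # gradient accumulators at encoder stage outputs
  # decoder stages, shallowest first (reverse of forward execution order)
  for (s in seq_len(n - 1L)) {
    dc <- cache$dec[[s]]
    pre <- paste0("dec", s)
    dScOut <- dCur
    dResBase <- dCur
    sb <- scseBackward(dScOut, cseW(p, pre), sseW(p, pre), dc$scse)
    addG(paste0(pre, ".cse.W1"), sb$grads$cse$W1)
    addG(paste0(pre, ".cse.b1"), sb$grads$cse$b1)
    addG(paste0(pre, ".cse.W2"), sb$grads$cse$W2)
    addG(paste0(pre, ".cse.b2"), sb$grads$cse$b2)
    addG(paste0(pre, ".sse.w"), sb$grads$sse$w)
    addG(paste0(pre, ".sse.b"), sb$grads$sse$b)
    dConv <- sb$dX
    for (j in 2:1) {
      cb <- convReluBackward(dConv, p[[sprintf("%s.conv%d.W", pre, j)]],
                             dc$convs[[j]])
      addG(sprintf("%s.conv%d.W", pre, j), cb$dW)
      addG(sprintf("%s.conv%d.b", pre, j), cb$db)
      dConv <- cb$dX
    }
    if (cfg@skipFusion == "add") {
      dT0 <- dConv + dResBase
      dUp <- dT0
      dEnc[[s]] <- dT0
    } else {
      dd <- dim(dConv)
      C <- dd[4] %/% 2L
      dUp <- dConv[, , , seq_len(C), drop = FALSE] + dResBase
      dEnc[[s]] <- dConv[, , , C + seq_len(C), drop = FALSE]
    }
    ub <- convTReluBackward(dUp, p[[sprintf("up%d.U", s)]], dc$up)
    addG(sprintf("up%d.U", s), ub$dU)
    addG(sprintf("up%d.b", s), ub$db)
    dCur <- ub$dX
  }
  # non-local block at the bottleneck
  nb <- nonlocalBackward(dCur, nlW(p, cfg@nonlocalResidual), cache$nl)
  for (nm in names(nb$grads)) addG(paste0("nl.", nm), nb$grads[[nm]])
  dEnc[[n]] <- nb$dX
  # encoder stages, deepest first
  for (s in rev(seq_len(n))) {
    ec <- cache$enc[[s]]
    pre <- paste0("enc", s)
    dOut <- dEnc[[s]]
    sb <- scseBackward(dOut, cseW(p, pre), sseW(p, pre), ec$scse)
    addG(paste0(pre, ".cse.W1"), sb$grads$cse$W1)
    addG(paste0(pre, ".cse.b1"), sb$grads$cse$b1)
    addG(paste0(pre, ".cse.W2"), sb$grads$cse$W2)
    addG(paste0(pre, ".cse.b2"), sb$grads$cse$b2)
    addG(paste0(pre, ".sse.w"), sb$grads$sse$w)
    addG(paste0(pre, ".sse.b"), sb$grads$sse$b)
    dConv <- sb$dX
    nconv <- if (s == 1L) 1L else 2L
    for (j in rev(seq_len(nconv))) {
      cb <- convReluBackward(dConv, p[[sprintf("%s.conv%d.W", pre, j)]],
                             ec$convs[[j]])
      addG(sprintf("%s.conv%d.W", pre, j), cb$dW)
      addG(sprintf("%s.conv%d.b", pre, j), cb$db)
      dConv <- cb$dX
    }
    dStageIn <- dConv + dOut # residual shortcut
    if (s > 1L) {
      db <- convReluBackward(dStageIn, p[[sprintf("down%d.W", s - 1L)]],
                             cache$enc[[s - 1L]]$down)
      addG(sprintf("down%d.W", s - 1L), db$dW)
      addG(sprintf("down%d.b", s - 1L), db$db)
      dEnc[[s - 1L]] <- if (is.null(dEnc[[s - 1L]])) db$dX
                        else dEnc[[s - 1L]] + db$dX
    } else {
      sb2 <- convReluBackward(dStageIn, p[["stem.W"]], cache$stem)
      addG("stem.W", sb2$dW)
      addG("stem.b", sb2$db)
    }
  }
  g
}
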