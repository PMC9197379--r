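# Attention blocks: concurrent spatial/channel squeeze-and-excitation (scSE)
# and the non-local self-attention block.  All blocks map a feature map
# (D, W, H, C) to a feature map of identical shape, so they can be dropped
# into any network stage.  Each exported forward has an internal cached
# variant plus a hand-derived backward used by the training loop.

#' Channel SE weights
#'
#' Parameters of the channel squeeze-and-excitation (cSE) bottleneck: a
#' two-layer fully connected net, C -> C/r -> C, with reduction ratio r.
#'
#' @param C channel count; must be divisible by \code{r}.
#' @param r reduction ratio (default 4).
#' @param init \code{"truncnorm"} (seedable fan-in truncated normal) or
#'   \code{"zero"}.
#' @return List with \code{W1} (C/r x C), \code{b1}, \code{W2} (C x C/r),
#'   \code{b2}, and \code{r}.
#' @export
cseWeights <- function(C, r = 4L, init = c("truncnorm", "zero")) {
  init <- match.arg(init)
  if (C %% r != 0) configError("channels (%d) not divisible by reduction r=%d", C, r)
  h <- C %/% r
  if (init == "zero") {
    list(W1 = matrix(0, h, C), b1 = numeric(h),
         W2 = matrix(0, C, h), b2 = numeric(C), r = as.integer(r))
  } else {
    list(W1 = matrix(initTruncNormal(h * C, C), h, C), b1 = numeric(h),
         W2 = matrix(initTruncNormal(C * h, h), C, h), b2 = numeric(C),
         r = as.integer(r))
  }
}

#' Spatial SE weights
#'
#' Parameters of the spatial squeeze-and-excitation (sSE) gate: a single
#' 1x1x1 convolution collapsing C channels to one gating map.
#'
#' @inheritParams cseWeights
#' @return List with \code{w} (C x 1) and scalar \code{b}.
#' @export
sseWeights <- function(C, init = c("truncnorm", "zero")) {
  init <- match.arg(init)
  w <- if (init == "zero") matrix(0, C, 1)
       else matrix(initTruncNormal(C, C), C, 1)
  list(w = w, b = 0)
}

#' Non-local block weights
#'
#' 1x1x1 projections theta, phi, g from C to C/2 channels, and the output
#' projection z from C/2 back to C.
#'
#' @param C channel count; must be even.
#' @param residual if \code{TRUE}, the block output is \code{z + x}; default
#'   \code{FALSE} (pure projection output).
#' @inheritParams cseWeights
#' @return List of projection matrices and biases plus the \code{residual}
#'   flag.
#' @export
nonlocalWeights <- function(C, residual = FALSE, init = c("truncnorm", "zero")) {
  init <- match.arg(init)
  if (C %% 2 != 0) channelParityError("non-local block needs even channels, got %d", C)
  h <- C %/% 2
  mk <- function(nr, nc) if (init == "zero") matrix(0, nr, nc)
                         else matrix(initTruncNormal(nr * nc, nr), nr, nc)
  list(Wtheta = mk(C, h), btheta = numeric(h),
       Wphi   = mk(C, h), bphi   = numeric(h),
       Wg     = mk(C, h), bg     = numeric(h),
       Wz     = mk(h, C), bz     = numeric(C),
       residual = isTRUE(residual))
}

#' Channel squeeze: global average pooling
#'
#' Compresses a (D, W, H, C) feature map to one value per channel — the mean
#' over all D*W*H spatial positions (the 1x1x1xC squeeze).
#'
#' @param x numeric array (D, W, H, C).
#' @return Numeric vector of length C.
#' @export
cseSqueeze <- function(x) {
  colMeans(asPositionMatrix(x))
}

#' Channel excitation: bottleneck gate from the squeezed vector
#'
#' Two fully connected layers produce a per-channel gate in (0, 1).  The
#' default order applies ReLU after the first layer and sigmoid after the
#' second (the standard SE form, required for multiplicative gating);
#' \code{order = "literal"} applies sigmoid first and ReLU last instead.
#'
#' @param s channel vector of length C.
#' @param w weights from [cseWeights()].
#' @param order \code{"sigmoid_last"} (default) or \code{"literal"}.
#' @return Gate vector of length C.
#' @export
cseExcite <- function(s, w, order = c("sigmoid_last", "literal")) {
  order <- match.arg(order)
  if (length(s) != ncol(w$W1))
    shapeMismatchError("squeeze vector length %d, cSE expects %d",
                       length(s), ncol(w$W1))
  if (order == "sigmoid_last") {
    h <- relu(as.vector(w$W1 %*% s + w$b1))
    sigmoid(as.vector(w$W2 %*% h + w$b2))
  } else {
    h <- sigmoid(as.vector(w$W1 %*% s + w$b1))
    relu(as.vector(w$W2 %*% h + w$b2))
  }
}

#' Channel squeeze-and-excitation forward
#'
#' Scales every channel of the input by its excitation gate:
#' \code{out[d,w,h,c] = gate_c * x[d,w,h,c]}.
#'
#' @inheritParams cseSqueeze
#' @param w weights from [cseWeights()].
#' @param order see [cseExcite()].
#' @return Array of the same shape as \code{x}.
#' @export
cseForward <- function(x, w, order = "sigmoid_last") {
  gate <- cseExcite(cseSqueeze(x), w, order)
  d <- dim(x)
  array(asPositionMatrix(x) * rep(gate, each = prod(d[1:3])), d)
}

#' Spatial squeeze-and-excitation forward
#'
#' A 1x1x1 convolution collapses the channels to a single spatial gate
#' \code{sigmoid(sum_c w_c x[d,w,h,c] + b)} of shape D x W x H x 1, which then
#' scales every channel at that position.
#'
#' @inheritParams cseForward
#' @param w weights from [sseWeights()].
#' @return Array of the same shape as \code{x}.
#' @export
sseForward <- function(x, w) {
  d <- dim(x)
  if (nrow(w$w) != d[4])
    shapeMismatchError("sSE weights expect %d channels, input has %d",
                       nrow(w$w), d[4])
  X <- asPositionMatrix(x)
  gate <- sigmoid(as.vector(X %*% w$w + w$b))
  array(X * gate, d)
}

#' Concurrent spatial and channel SE forward
#'
#' The scSE block: the cSE and sSE branches see the same input and their
#' outputs are summed.  With zero-initialized weights both gates are 0.5, so
#' the block is the identity map.
#'
#' @inheritParams cseForward
#' @param wc cSE weights ([cseWeights()]).
#' @param ws sSE weights ([sseWeights()]).
#' @return Array of the same shape as \code{x}.
#' @export
scseForward <- function(x, wc, ws, order = "sigmoid_last") {
  cseForward(x, wc, order) + sseForward(x, ws)
}

#' Non-local self-attention forward
#'
#' Dot-product self-attention over all N = D*W*H spatial positions.  The
#' input is projected to half the channels by the 1x1x1 convolutions theta,
#' phi and g; the attention matrix is the row-softmax of theta phi^T
#' (normalized over the enumerated position j); the attended features
#' y = A g are projected back to C channels by the 1x1x1 convolution z.
#' With \code{residual = TRUE} in the weights, the input is added back.
#'
#' @inheritParams cseForward
#' @param w weights from [nonlocalWeights()].
#' @param returnAttention also return the N x N attention matrix.
#' @return Array of the same shape as \code{x}; if \code{returnAttention},
#'   a list with \code{out} and \code{attention}.
#' @export
nonlocalForward <- function(x, w, returnAttention = FALSE) {
  d <- dim(x)
  C <- d[4]
  if (C %% 2 != 0) channelParityError("non-local block needs even channels, got %d", C)
  if (nrow(w$Wtheta) != C)
    shapeMismatchError("non-local weights expect %d channels, input has %d",
                       nrow(w$Wtheta), C)
  X <- asPositionMatrix(x)                             # N x C
  theta <- sweep(X %*% w$Wtheta, 2, w$btheta, "+")     # N x C/2
  phi   <- sweep(X %*% w$Wphi,   2, w$bphi,   "+")
  g     <- sweep(X %*% w$Wg,     2, w$bg,     "+")
  A <- rowSoftmax(theta %*% t(phi))                    # N x N
  y <- A %*% g                                         # N x C/2
  z <- sweep(y %*% w$Wz, 2, w$bz, "+")                 # N x C
  if (w$residual) z <- z + X
  out <- array(z, d)
  if (returnAttention) list(out = out, attention = A) else out
}

# ---- cached forwards and backwards (internal, used by the network) ---------

scseForwardCache <- function(x, wc, ws) {
  d <- dim(x)
  N <- prod(d[1:3])
  X <- asPositionMatrix(x)
  s <- colMeans(X)
  hPre <- as.vector(wc$W1 %*% s + wc$b1)
  h <- relu(hPre)
  gate <- sigmoid(as.vector(wc$W2 %*% h + wc$b2))
  q <- as.vector(X %*% ws$w + ws$b)
  gs <- sigmoid(q)
  out <- X * rep(gate, each = N) + X * gs
  list(out = array(out, d),
       cache = list(X = X, s = s, hPre = hPre, h = h, gate = gate,
                    gs = gs, d = d))
}

scseBackward <- function(dOut, wc, ws, cache) {
  d <- cache$d
  N <- prod(d[1:3])
  dY <- matrix(dOut, N, d[4])
  X <- cache$X
  gate <- cache$gate
  gs <- cache$gs
  # cSE branch
  dX <- dY * rep(gate, each = N)
  dGate <- colSums(dY * X)
  dGPre <- dGate * gate * (1 - gate)
  dW2 <- dGPre %o% cache$h
  db2 <- dGPre
  dH <- as.vector(t(wc$W2) %*% dGPre)
  dHPre <- dH * (cache$hPre > 0)
  dW1 <- dHPre %o% cache$s
  db1 <- dHPre
  dS <- as.vector(t(wc$W1) %*% dHPre)
  dX <- dX + matrix(dS / N, N, d[4], byrow = TRUE)
  # sSE branch
  dX <- dX + dY * gs
  dQ <- rowSums(dY * X) * gs * (1 - gs)
  dX <- dX + dQ %*% t(ws$w) # gate depends on X too
  dw <- t(X) %*% dQ
  db <- sum(dQ)
  list(dX = array(dX, d),
       grads = list(cse = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
                    sse = list(w = dw, b = db)))
}

nonlocalForwardCache <- function(x, w) {
  d <- dim(x)
  X <- asPositionMatrix(x)
  theta <- sweep(X %*% w$Wtheta, 2, w$btheta, "+")
  phi   <- sweep(X %*% w$Wphi,   2, w$bphi,   "+")
  g     <- sweep(X %*% w$Wg,     2, w$bg,     "+")
  A <- rowSoftmax(theta %*% t(phi))
  y <- A %*% g
  z <- sweep(y %*% w$Wz, 2, w$bz, "+")
  if (w$residual) z <- z + X
  list(out = array(z, d),
       cache = list(X = X, theta = theta, phi = phi, g = g, A = A, y = y,
                    d = d))
}

nonlocalBackward <- function(dOut, w, cache) {
  d <- cache$d
  N <- prod(d[1:3])
  dZ <- matrix(dOut, N, d[4])
  X <- cache$X; A <- cache$A
  dY <- dZ %*% t(w$Wz)
  dWz <- t(cache$y) %*% dZ
  dbz <- colSums(dZ)
  dA <- dY %*% t(cache$g)
  dG <- t(A) %*% dY
  dScore <- A * (dA - rowSums(dA * A)) # softmax Jacobian, row-wise
  dTheta <- dScore %*% cache$phi
  dPhi <- t(dScore) %*% cache$theta
  dX <- dTheta %*% t(w$Wtheta) + dPhi %*% t(w$Wphi) + dG %*% t(w$Wg)
  if (w$residual) dX <- dX + dZ
  list(dX = array(dX, d),
       grads = list(Wtheta = t(X) %*% dTheta, btheta = colSums(dTheta),
                    Wphi = t(X) %*% dPhi, bphi = colSums(dPhi),
                    Wg = t(X) %*% dG, bg = colSums(dG),
                    Wz = dWz, bz = dbz))
}
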