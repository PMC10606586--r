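# Minimal neural-network primitives in base-R matrix algebra: dense,
# batch-norm, dropout, 3x3 same-padding convolution (im2col), 2x2 average
# pooling, global mean+max pooling, weighted softmax cross-entropy, and SGD
# with momentum. Gradients are validated against finite differences in the
# test suite.

# broadcast a length-d vector across the B rows of a B x d matrix
bcastRow <- function(v, B) rep(v, each = B)

heInit <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

linearInit <- function(nin, nout, bias = TRUE) {
  list(W = heInit(nin, nout), b = if (bias) numeric(nout) else NULL,
       vW = matrix(0, nin, nout), vb = if (bias) numeric(nout) else NULL)
}

linearForward <- function(layer, x) {
  y <- x %*% layer$W
  if (!is.null(layer$b)) y <- y + bcastRow(layer$b, nrow(x))
  y
}

# returns list(dx, dW, db)
linearBackward <- function(layer, x, dy) {
  list(dx = dy %*% t(layer$W), dW = crossprod(x, dy),
       db = if (!is.null(layer$b)) colSums(dy) else NULL)
}

sgdUpdate <- function(layer, dW, db, lr, mom) {
  layer$vW <- mom * layer$vW - lr * dW
  layer$W <- layer$W + layer$vW
  if (!is.null(db)) {
    layer$vb <- mom * layer$vb - lr * db
    layer$b <- layer$b + layer$vb
  }
  layer
}

# ---- batch normalisation (per feature) ------------------------------------

bnInit <- function(d) {
  list(gamma = rep(1, d), beta = numeric(d), rmean = numeric(d),
       rvar = rep(1, d), eps = 1e-5, bnm = 0.1,
       vgamma = numeric(d), vbeta = numeric(d))
}

bnForward <- function(layer, x, train) {
  B <- nrow(x)
  if (train) {
    mu <- colMeans(x)
    xc <- x - bcastRow(mu, B)
    v <- colMeans(xc * xc)
    layer$rmean <- (1 - layer$bnm) * layer$rmean + layer$bnm * mu
    layer$rvar <- (1 - layer$bnm) * layer$rvar + layer$bnm * v
  } else {
    mu <- layer$rmean
    v <- layer$rvar
    xc <- x - bcastRow(mu, B)
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- xc * bcastRow(istd, B)
  y <- xhat * bcastRow(layer$gamma, B) + bcastRow(layer$beta, B)
  list(layer = layer, y = y, cache = list(xhat = xhat, istd = istd))
}

bnBackward <- function(layer, cache, dy) {
  B <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * bcastRow(layer$gamma, B)
  dx <- (dxhat - bcastRow(colMeans(dxhat), B) -
           xhat * bcastRow(colMeans(dxhat * xhat), B)) *
    bcastRow(cache$istd, B)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bnUpdate <- function(layer, dgamma, dbeta, lr, mom) {
  layer$vgamma <- mom * layer$vgamma - lr * dgamma
  layer$gamma <- layer$gamma + layer$vgamma
  layer$vbeta <- mom * layer$vbeta - lr * dbeta
  layer$beta <- layer$beta + layer$vbeta
  layer
}

# ---- dropout ---------------------------------------------------------------

dropoutForward <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((stats::runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

# ---- 3x3 same-padding convolution via im2col -------------------------------

.convCache <- new.env(parent = emptyenv())

im2colIdx <- function(H, W, Ci, B) {
  key <- paste(H, W, Ci, B, sep = "x")
  idx <- .convCache[[key]]
  if (!is.null(idx)) return(idx)
  Hp <- H + 2L
  Wp <- W + 2L
  offs <- as.vector(outer(0:2, (0:2) * Hp, "+"))
  rowpart <- rep(offs, Ci) + rep((seq_len(Ci) - 1L) * (Hp * Wp), each = 9L)
  base <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))
  colpart <- rep(base, B) + rep((seq_len(B) - 1L) * (Hp * Wp * Ci),
                                each = H * W)
  idx <- outer(as.integer(rowpart), as.integer(colpart), "+")
  .convCache[[key]] <- idx
  idx
}

convInit <- function(cin, cout) {
  fanin <- 9 * cin
  list(W = matrix(stats::rnorm(cout * fanin, sd = sqrt(2 / fanin)),
                  cout, fanin),
       b = numeric(cout), vW = matrix(0, cout, fanin), vb = numeric(cout),
       cin = cin, cout = cout)
}

padSpatial <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  xp
}

convForward <- function(layer, x) {
  d <- dim(x) # H W Ci B
  Xcol <- matrix(padSpatial(x)[im2colIdx(d[1], d[2], d[3], d[4])],
                 nrow = 9L * d[3])
  y <- layer$W %*% Xcol + layer$b
  out <- aperm(array(y, c(layer$cout, d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(y = out, Xcol = Xcol, dims = d)
}

convBackward <- function(layer, cache, dy) {
  d <- cache$dims
  Co <- layer$cout
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = Co)
  dW <- tcrossprod(dym, cache$Xcol)
  db <- rowSums(dym)
  # gradient w.r.t. input = same-padding convolution of dy with the
  # spatially flipped, channel-transposed kernel
  Warr <- array(layer$W, c(Co, 3, 3, layer$cin))
  Wt <- matrix(aperm(Warr[, 3:1, 3:1, , drop = FALSE], c(4, 2, 3, 1)),
               nrow = layer$cin)
  dyCol <- matrix(padSpatial(dy)[im2colIdx(d[1], d[2], Co, d[4])],
                  nrow = 9L * Co)
  dx <- aperm(array(Wt %*% dyCol, c(layer$cin, d[1], d[2], d[4])),
              c(2, 3, 1, 4))
  list(dx = dx, dW = dW, db = db)
}

# ---- 2x2 average pooling ----------------------------------------------------

avgPoolForward <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  y <- (x[io, jo, , , drop = FALSE] + x[io + 1L, jo, , , drop = FALSE] +
          x[io, jo + 1L, , , drop = FALSE] +
          x[io + 1L, jo + 1L, , , drop = FALSE]) / 4
  y
}

avgPoolBackward <- function(dy, inDims) {
  dx <- array(0, inDims)
  io <- seq(1L, inDims[1], by = 2L)
  jo <- seq(1L, inDims[2], by = 2L)
  q <- dy / 4
  dx[io, jo, , ] <- q
  dx[io + 1L, jo, , ] <- q
  dx[io, jo + 1L, , ] <- q
  dx[io + 1L, jo + 1L, , ] <- q
  dx
}

# ---- global mean + max pooling ---------------------------------------------

globalPoolForward <- function(x) {
  d <- dim(x) # H W C B
  hw <- d[1] * d[2]
  xm <- matrix(x, nrow = hw)                    # hw x (C*B)
  mn <- colMeans(xm)
  amax <- max.col(t(xm), ties.method = "first") # argmax per column
  mx <- xm[cbind(amax, seq_len(ncol(xm)))]
  feats <- cbind(t(matrix(mn, d[3], d[4])), t(matrix(mx, d[3], d[4])))
  list(y = feats, amax = amax, dims = d)
}

globalPoolBackward <- function(cache, dfeats) {
  d <- cache$dims
  hw <- d[1] * d[2]
  C <- d[3]
  dmean <- dfeats[, seq_len(C), drop = FALSE]   # B x C
  dmax <- dfeats[, C + seq_len(C), drop = FALSE]
  dmeanCol <- as.vector(t(dmean))               # ordered (c fastest, then b)
  dmaxCol <- as.vector(t(dmax))
  dxm <- matrix(rep(dmeanCol, each = hw) / hw, nrow = hw)
  ij <- cbind(cache$amax, seq_len(ncol(dxm)))
  dxm[ij] <- dxm[ij] + dmaxCol
  array(dxm, d)
}

# ---- weighted softmax cross-entropy ----------------------------------------

softmaxRows <- function(z) {
  m <- apply(z, 1, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# labels 0-based; w per-class weights; mean over the batch of w[y]*CE
weightedCeLoss <- function(logits, labels, w) {
  n <- nrow(logits)
  C <- ncol(logits)
  if (any(labels < 0L) || any(labels >= C)) {
    validationError(sprintf("pseudo-labels must lie in [0, %d)", C))
  }
  p <- softmaxRows(logits)
  iy <- cbind(seq_len(n), labels + 1L)
  wy <- w[labels + 1L]
  loss <- mean(-wy * log(pmax(p[iy], 1e-12)))
  dlogits <- p * (wy / n)
  dlogits[iy] <- dlogits[iy] - wy / n
  list(loss = loss, dlogits = dlogits)
}
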