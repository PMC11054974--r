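#' @include utils.R
NULL

## ---------------------------------------------------------------------------
## Compact neural-network engine: layer primitives.
##
## Activations are numeric arrays in these shapes:
##   2-D feature maps : [H, W, C, B]
##   1-D feature maps : [L, C, B]
##   dense            : [B, D]
##   recurrent input  : [T, D, B]
## All heavy operations reduce to BLAS matrix products via im2col; the
## layers carry their own parameters, gradients and forward caches so that
## a network is a plain list of layers.
## ---------------------------------------------------------------------------

sigm <- function(x) 1 / (1 + exp(-x))

## --- initialisers (He for conv/linear, uniform for LSTM) -------------------

initConv2d <- function(k, cin, cout, first = FALSE) {
  W <- matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  list(type = "conv2d", k = k, pad = (k - 1L) %/% 2L, cin = cin, cout = cout,
       W = W, b = numeric(cout), first = first, cache = NULL, grads = NULL)
}

initConv1d <- function(k, cin, cout, first = FALSE) {
  W <- matrix(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
              k * cin, cout)
  list(type = "conv1d", k = k, pad = (k - 1L) %/% 2L, cin = cin, cout = cout,
       W = W, b = numeric(cout), first = first, cache = NULL, grads = NULL)
}

initLinear <- function(din, dout) {
  list(type = "linear",
       W = matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
       b = numeric(dout), cache = NULL, grads = NULL)
}

initBatchNorm <- function(d, kind = c("fc", "conv1d", "conv2d"),
                          momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", kind = match.arg(kind), d = d,
       gamma = rep(1, d), beta = numeric(d),
       runMean = numeric(d), runVar = rep(1, d),
       momentum = momentum, eps = eps, cache = NULL, grads = NULL)
}

initRelu <- function() list(type = "relu", cache = NULL)
initDropout <- function(p) list(type = "dropout", p = p, cache = NULL)
initFlatten <- function() list(type = "flatten", cache = NULL)
initMaxPool2d <- function() list(type = "maxpool2d", cache = NULL)
initMaxPool1d <- function() list(type = "maxpool1d", cache = NULL)
initGlobalMaxPool1d <- function() list(type = "gmaxpool1d", cache = NULL)

initLSTM <- function(din, hidden) {
  r <- 1 / sqrt(hidden)
  u <- function(n) stats::runif(n, -r, r)
  b <- numeric(4 * hidden)
  b[hidden + seq_len(hidden)] <- 1      # forget-gate bias
  list(type = "lstm", din = din, hidden = hidden,
       Wx = matrix(u(din * 4 * hidden), din, 4 * hidden),
       Wh = matrix(u(hidden * 4 * hidden), hidden, 4 * hidden),
       b = b, cache = NULL, grads = NULL)
}

initResidual <- function(sub) {
  list(type = "residual", sub = sub, cache = NULL)
}

## --- im2col index tables ---------------------------------------------------

im2colIndex2d <- function(H, W, C, k, p) {
  Hp <- H + 2L * p; Wp <- W + 2L * p
  pos_i <- rep(seq_len(H), times = W)
  pos_j <- rep(seq_len(W), each = H)
  base <- pos_i + Hp * (pos_j - 1)
  off <- expand.grid(di = 0:(k - 1), dj = 0:(k - 1), c = 0:(C - 1))
  offv <- off$di + Hp * off$dj + Hp * Wp * off$c
  outer(base, offv, "+")
}

im2colIndex1d <- function(L, C, k, p) {
  Lp <- L + 2L * p
  base <- seq_len(L)
  off <- expand.grid(di = 0:(k - 1), c = 0:(C - 1))
  offv <- off$di + Lp * off$c
  outer(base, offv, "+")
}

convIdx <- function(layer, dims) {
  cached <- layer$.idx
  if (!is.null(cached) && identical(attr(cached, "dims"), dims))
    return(cached)
  idx <- if (layer$type == "conv2d")
    im2colIndex2d(dims[1], dims[2], dims[3], layer$k, layer$pad)
  else
    im2colIndex1d(dims[1], dims[2], layer$k, layer$pad)
  attr(idx, "dims") <- dims
  attr(idx, "ug") <- sort(unique(as.vector(idx)))
  idx
}

## --- forward / backward per type -------------------------------------------

fwdConv2d <- function(layer, x, training) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  stopifnot(C == layer$cin)
  p <- layer$pad
  Hp <- H + 2L * p; Wp <- W + 2L * p
  idx <- convIdx(layer, d[1:3])
  layer$.idx <- idx
  xp <- array(0, c(Hp, Wp, C, B))
  xp[p + seq_len(H), p + seq_len(W), , ] <- x
  npos <- H * W
  sampleStride <- Hp * Wp * C
  out <- array(0, c(H, W, layer$cout, B))
  cols <- if (training) vector("list", B) else NULL
  bias <- rep(layer$b, each = npos)
  for (bb in seq_len(B)) {
    cb <- matrix(xp[(bb - 1) * sampleStride + idx], npos)
    ob <- cb %*% layer$W + bias
    out[, , , bb] <- ob
    if (training) cols[[bb]] <- cb
  }
  layer$cache <- if (training) list(cols = cols, dims = d) else NULL
  list(layer = layer, out = out)
}

bwdConv2d <- function(layer, dout) {
  d <- layer$cache$dims
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  p <- layer$pad; Hp <- H + 2L * p; Wp <- W + 2L * p
  idx <- layer$.idx
  ug <- attr(idx, "ug")
  npos <- H * W
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  db <- numeric(layer$cout)
  dx <- NULL
  if (!isTRUE(layer$first))
    dx <- array(0, c(H, W, C, B))
  idxVec <- as.vector(idx)
  for (bb in seq_len(B)) {
    dob <- matrix(dout[, , , bb], npos)
    cb <- layer$cache$cols[[bb]]
    dW <- dW + crossprod(cb, dob)
    db <- db + colSums(dob)
    if (!is.null(dx)) {
      dcols <- dob %*% t(layer$W)
      acc <- rowsum(as.vector(dcols), idxVec, reorder = TRUE)
      dxp <- numeric(Hp * Wp * C)
      dxp[ug] <- acc[, 1]
      dxp <- array(dxp, c(Hp, Wp, C))
      dx[, , , bb] <- dxp[p + seq_len(H), p + seq_len(W), ]
    }
  }
  layer$grads <- list(W = dW, b = db)
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

fwdConv1d <- function(layer, x, training) {
  d <- dim(x); L <- d[1]; C <- d[2]; B <- d[3]
  stopifnot(C == layer$cin)
  p <- layer$pad; Lp <- L + 2L * p
  idx <- convIdx(layer, d[1:2])
  layer$.idx <- idx
  xp <- array(0, c(Lp, C, B))
  xp[p + seq_len(L), , ] <- x
  sampleStride <- Lp * C
  out <- array(0, c(L, layer$cout, B))
  cols <- if (training) vector("list", B) else NULL
  bias <- rep(layer$b, each = L)
  for (bb in seq_len(B)) {
    cb <- matrix(xp[(bb - 1) * sampleStride + idx], L)
    out[, , bb] <- cb %*% layer$W + bias
    if (training) cols[[bb]] <- cb
  }
  layer$cache <- if (training) list(cols = cols, dims = d) else NULL
  list(layer = layer, out = out)
}

bwdConv1d <- function(layer, dout) {
  d <- layer$cache$dims
  L <- d[1]; C <- d[2]; B <- d[3]
  p <- layer$pad; Lp <- L + 2L * p
  idx <- layer$.idx
  ug <- attr(idx, "ug")
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  db <- numeric(layer$cout)
  dx <- if (isTRUE(layer$first)) NULL else array(0, c(L, C, B))
  idxVec <- as.vector(idx)
  for (bb in seq_len(B)) {
    dob <- matrix(dout[, , bb], L)
    cb <- layer$cache$cols[[bb]]
    dW <- dW + crossprod(cb, dob)
    db <- db + colSums(dob)
    if (!is.null(dx)) {
      dcols <- dob %*% t(layer$W)
      acc <- rowsum(as.vector(dcols), idxVec, reorder = TRUE)
      dxp <- numeric(Lp * C)
      dxp[ug] <- acc[, 1]
      dxp <- array(dxp, c(Lp, C))
      dx[, , bb] <- dxp[p + seq_len(L), ]
    }
  }
  layer$grads <- list(W = dW, b = db)
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

fwdMaxPool2d <- function(layer, x, training) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ro <- seq_len(H2) * 2L - 1L; re <- seq_len(H2) * 2L
  co <- seq_len(W2) * 2L - 1L; ce <- seq_len(W2) * 2L
  x1 <- x[ro, co, , , drop = FALSE]; x2 <- x[re, co, , , drop = FALSE]
  x3 <- x[ro, ce, , , drop = FALSE]; x4 <- x[re, ce, , , drop = FALSE]
  out <- pmax(x1, x2, x3, x4)
  if (training) {
    m1 <- x1 == out
    m2 <- !m1 & (x2 == out)
    m3 <- !m1 & !m2 & (x3 == out)
    m4 <- !m1 & !m2 & !m3
    layer$cache <- list(dims = d, masks = list(m1, m2, m3, m4))
  } else layer$cache <- NULL
  list(layer = layer, out = out)
}

bwdMaxPool2d <- function(layer, dout) {
  d <- layer$cache$dims
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ro <- seq_len(H2) * 2L - 1L; re <- seq_len(H2) * 2L
  co <- seq_len(W2) * 2L - 1L; ce <- seq_len(W2) * 2L
  ms <- layer$cache$masks
  dx <- array(0, d)
  tmp <- dout; tmp[!ms[[1]]] <- 0; dx[ro, co, , ] <- tmp
  tmp <- dout; tmp[!ms[[2]]] <- 0; dx[re, co, , ] <- tmp
  tmp <- dout; tmp[!ms[[3]]] <- 0; dx[ro, ce, , ] <- tmp
  tmp <- dout; tmp[!ms[[4]]] <- 0; dx[re, ce, , ] <- tmp
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

fwdMaxPool1d <- function(layer, x, training) {
  d <- dim(x)
  L2 <- d[1] %/% 2L
  io <- seq_len(L2) * 2L - 1L; ie <- seq_len(L2) * 2L
  x1 <- x[io, , , drop = FALSE]; x2 <- x[ie, , , drop = FALSE]
  out <- pmax(x1, x2)
  if (training) {
    m1 <- x1 == out
    layer$cache <- list(dims = d, m1 = m1)
  } else layer$cache <- NULL
  list(layer = layer, out = out)
}

bwdMaxPool1d <- function(layer, dout) {
  d <- layer$cache$dims
  L2 <- d[1] %/% 2L
  io <- seq_len(L2) * 2L - 1L; ie <- seq_len(L2) * 2L
  m1 <- layer$cache$m1
  dx <- array(0, d)
  tmp <- dout; tmp[!m1] <- 0; dx[io, , ] <- tmp
  tmp <- dout; tmp[m1] <- 0; dx[ie, , ] <- tmp
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

fwdGlobalMaxPool1d <- function(layer, x, training) {
  d <- dim(x)                            # [L, C, B]
  xm <- matrix(x, d[1])                  # L x (C*B)
  amax <- max.col(t(xm), ties.method = "first")
  mx <- xm[cbind(amax, seq_len(ncol(xm)))]
  out <- t(matrix(mx, d[2], d[3]))       # B x C
  if (training) layer$cache <- list(dims = d, amax = amax)
  else layer$cache <- NULL
  list(layer = layer, out = out)
}

bwdGlobalMaxPool1d <- function(layer, dout) {
  d <- layer$cache$dims
  amax <- layer$cache$amax
  dx <- array(0, d)
  dv <- as.vector(t(dout))               # C*B in column order of xm
  dxm <- matrix(0, d[1], d[2] * d[3])
  dxm[cbind(amax, seq_along(amax))] <- dv
  dx[] <- dxm
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

fwdFlatten <- function(layer, x, training) {
  d <- dim(x)
  B <- d[length(d)]
  out <- t(matrix(x, ncol = B))
  if (training) layer$cache <- list(dims = d)
  else layer$cache <- NULL
  list(layer = layer, out = out)
}

bwdFlatten <- function(layer, dout) {
  d <- layer$cache$dims
  dx <- array(t(dout), d)
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

fwdLinear <- function(layer, x, training) {
  out <- x %*% layer$W + rep(layer$b, each = nrow(x))
  layer$cache <- if (training) list(x = x) else NULL
  list(layer = layer, out = out)
}

bwdLinear <- function(layer, dout) {
  x <- layer$cache$x
  layer$grads <- list(W = crossprod(x, dout), b = colSums(dout))
  dx <- dout %*% t(layer$W)
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

fwdRelu <- function(layer, x, training) {
  out <- x
  neg <- x < 0
  out[neg] <- 0
  layer$cache <- if (training) list(neg = neg) else NULL
  list(layer = layer, out = out)
}

bwdRelu <- function(layer, dout) {
  dout[layer$cache$neg] <- 0
  layer$cache <- NULL
  list(layer = layer, dx = dout)
}

fwdDropout <- function(layer, x, training) {
  if (!training || layer$p <= 0) {
    layer$cache <- NULL
    return(list(layer = layer, out = x))
  }
  keep <- array(stats::runif(length(x)) >= layer$p, dim(x) %||% length(x))
  out <- x * keep / (1 - layer$p)
  layer$cache <- list(keep = keep)
  list(layer = layer, out = out)
}

bwdDropout <- function(layer, dout) {
  if (is.null(layer$cache))
    return(list(layer = layer, dx = dout))
  dx <- dout * layer$cache$keep / (1 - layer$p)
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Batch normalisation: "fc" normalises each feature over the batch; the
## conv kinds normalise each channel over batch and spatial positions.
## Channel-last reshaping used by the conv kinds.
bnToMatrix <- function(x, kind) {
  d <- dim(x)
  if (kind == "conv1d")
    matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])
  else                                   # conv2d: [H, W, C, B]
    matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

bnFromMatrix <- function(xm, d, kind) {
  if (kind == "conv1d")
    aperm(array(xm, c(d[1], d[3], d[2])), c(1, 3, 2))
  else
    aperm(array(xm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

fwdBatchNorm <- function(layer, x, training) {
  conv <- layer$kind != "fc"
  if (conv) {
    d <- dim(x)
    xm <- bnToMatrix(x, layer$kind)
  } else xm <- x
  n <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)
    layer$runMean <- (1 - layer$momentum) * layer$runMean + layer$momentum * mu
    layer$runVar <- (1 - layer$momentum) * layer$runVar + layer$momentum * v
  } else {
    mu <- layer$runMean
    v <- layer$runVar
    xc <- xm - rep(mu, each = n)
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- xc * rep(invstd, each = n)
  outm <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
  if (conv) {
    out <- bnFromMatrix(outm, d, layer$kind)
  } else out <- outm
  layer$cache <- if (training)
    list(xhat = xhat, invstd = invstd, dims = if (conv) d else NULL)
  else NULL
  list(layer = layer, out = out)
}

bwdBatchNorm <- function(layer, dout) {
  conv <- layer$kind != "fc"
  if (conv) {
    d <- layer$cache$dims
    dm <- bnToMatrix(dout, layer$kind)
  } else dm <- dout
  n <- nrow(dm)
  xhat <- layer$cache$xhat
  invstd <- layer$cache$invstd
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * rep(layer$gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dxm <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
    rep(invstd, each = n)
  if (conv) {
    dx <- bnFromMatrix(dxm, d, layer$kind)
  } else dx <- dxm
  layer$grads <- list(gamma = dgamma, beta = dbeta)
  layer$cache <- NULL
  list(layer = layer, dx = dx)
}

fwdLSTM <- function(layer, x, training) {
  d <- dim(x)                            # [T, Din, B]
  T_ <- d[1]; Din <- d[2]; B <- d[3]
  Hn <- layer$hidden
  h <- matrix(0, B, Hn); cc <- matrix(0, B, Hn)
  iH <- seq_len(Hn)
  cache <- if (training) vector("list", T_) else NULL
  bias <- rep(layer$b, each = B)
  for (t in seq_len(T_)) {
    xt <- t(matrix(x[t, , ], Din, B))
    z <- xt %*% layer$Wx + h %*% layer$Wh + bias
    ig <- sigm(z[, iH, drop = FALSE])
    fg <- sigm(z[, Hn + iH, drop = FALSE])
    gg <- tanh(z[, 2 * Hn + iH, drop = FALSE])
    og <- sigm(z[, 3 * Hn + iH, drop = FALSE])
    cprev <- cc
    cc <- fg * cc + ig * gg
    ct <- tanh(cc)
    hprev <- h
    h <- og * ct
    if (training)
      cache[[t]] <- list(xt = xt, hprev = hprev, cprev = cprev,
                         i = ig, f = fg, g = gg, o = og, ct = ct)
  }
  layer$cache <- if (training) list(steps = cache, dims = d) else NULL
  list(layer = layer, out = h)
}

bwdLSTM <- function(layer, dout) {
  d <- layer$cache$dims
  T_ <- d[1]; B <- d[3]; Hn <- layer$hidden
  steps <- layer$cache$steps
  dWx <- matrix(0, nrow(layer$Wx), ncol(layer$Wx))
  dWh <- matrix(0, nrow(layer$Wh), ncol(layer$Wh))
  db <- numeric(length(layer$b))
  dh <- dout
  dc <- matrix(0, B, Hn)
  for (t in rev(seq_len(T_))) {
    s <- steps[[t]]
    do_ <- dh * s$ct
    dc <- dc + dh * s$o * (1 - s$ct^2)
    di <- dc * s$g
    df <- dc * s$cprev
    dg <- dc * s$i
    dzi <- di * s$i * (1 - s$i)
    dzf <- df * s$f * (1 - s$f)
    dzg <- dg * (1 - s$g^2)
    dzo <- do_ * s$o * (1 - s$o)
    dz <- cbind(dzi, dzf, dzg, dzo)
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$hprev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% t(layer$Wh)
    dc <- dc * s$f
  }
  layer$grads <- list(Wx = dWx, Wh = dWh, b = db)
  layer$cache <- NULL
  list(layer = layer, dx = NULL)         # recurrent layer is always first
}

## --- dispatch ---------------------------------------------------------------

layerForward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv2d = fwdConv2d(layer, x, training),
    conv1d = fwdConv1d(layer, x, training),
    maxpool2d = fwdMaxPool2d(layer, x, training),
    maxpool1d = fwdMaxPool1d(layer, x, training),
    gmaxpool1d = fwdGlobalMaxPool1d(layer, x, training),
    flatten = fwdFlatten(layer, x, training),
    linear = fwdLinear(layer, x, training),
    relu = fwdRelu(layer, x, training),
    dropout = fwdDropout(layer, x, training),
    batchnorm = fwdBatchNorm(layer, x, training),
    lstm = fwdLSTM(layer, x, training),
    residual = fwdResidual(layer, x, training),
    stop("unknown layer type: ", layer$type))
}

layerBackward <- function(layer, dout) {
  switch(layer$type,
    conv2d = bwdConv2d(layer, dout),
    conv1d = bwdConv1d(layer, dout),
    maxpool2d = bwdMaxPool2d(layer, dout),
    maxpool1d = bwdMaxPool1d(layer, dout),
    gmaxpool1d = bwdGlobalMaxPool1d(layer, dout),
    flatten = bwdFlatten(layer, dout),
    linear = bwdLinear(layer, dout),
    relu = bwdRelu(layer, dout),
    dropout = bwdDropout(layer, dout),
    batchnorm = bwdBatchNorm(layer, dout),
    lstm = bwdLSTM(layer, dout),
    residual = bwdResidual(layer, dout),
    stop("unknown layer type: ", layer$type))
}

fwdResidual <- function(layer, x, training) {
  y <- x
  for (i in seq_along(layer$sub)) {
    r <- layerForward(layer$sub[[i]], y, training)
    layer$sub[[i]] <- r$layer
    y <- r$out
  }
  list(layer = layer, out = x + y)       # identity skip, pre-activation sum
}

bwdResidual <- function(layer, dout) {
  dy <- dout
  for (i in rev(seq_along(layer$sub))) {
    r <- layerBackward(layer$sub[[i]], dy)
    layer$sub[[i]] <- r$layer
    dy <- r$dx
  }
  list(layer = layer, dx = dout + dy)
}
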