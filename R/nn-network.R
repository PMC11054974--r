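#' @include nn-layers.R
NULL

## ---------------------------------------------------------------------------
## Network-level plumbing: a network is list(layers = <list>, tap = <int>),
## where `tap` indexes the layer whose output is the modality feature
## embedding. Training uses softmax cross-entropy and Adam.
## ---------------------------------------------------------------------------

netForward <- function(net, x, training = FALSE, upto = NULL) {
  n <- upto %||% length(net$layers)
  for (i in seq_len(n)) {
    r <- layerForward(net$layers[[i]], x, training)
    net$layers[[i]] <- r$layer
    x <- r$out
  }
  list(net = net, out = x)
}

netBackward <- function(net, dout) {
  for (i in rev(seq_along(net$layers))) {
    r <- layerBackward(net$layers[[i]], dout)
    net$layers[[i]] <- r$layer
    dout <- r$dx
    if (is.null(dout) && i > 1L)
      stop("internal: gradient vanished before reaching layer ", i - 1L)
  }
  net
}

## Feature-tap forward in evaluation mode.
netFeatures <- function(net, x) {
  netForward(net, x, training = FALSE, upto = net$tap)$out
}

softmaxCrossEntropy <- function(logits, y) {
  m <- apply(logits, 1, max)
  z <- exp(logits - m)
  p <- z / rowSums(z)
  n <- length(y)
  at <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[at], 1e-12)))
  grad <- p
  grad[at] <- grad[at] - 1
  grad <- grad / n
  list(loss = loss, grad = grad, probs = p)
}

softmaxProbs <- function(logits) {
  m <- apply(logits, 1, max)
  z <- exp(logits - m)
  z / rowSums(z)
}

## --- Adam -------------------------------------------------------------------

layerParamNames <- function(layer) {
  switch(layer$type,
         conv2d = , conv1d = , linear = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         lstm = c("Wx", "Wh", "b"),
         NULL)
}

adamInitLayer <- function(layer) {
  if (layer$type == "residual")
    return(list(sub = lapply(layer$sub, adamInitLayer)))
  nms <- layerParamNames(layer)
  if (is.null(nms)) return(NULL)
  st <- lapply(nms, function(nm) {
    p <- layer[[nm]]
    list(m = p * 0, v = p * 0)
  })
  names(st) <- nms
  st
}

adamStepLayer <- function(layer, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8) {
  if (layer$type == "residual") {
    for (i in seq_along(layer$sub)) {
      r <- adamStepLayer(layer$sub[[i]], st$sub[[i]], lr, t, beta1, beta2, eps)
      layer$sub[[i]] <- r$layer
      st$sub[i] <- list(r$st)          # keep NULL states in place
    }
    return(list(layer = layer, st = st))
  }
  nms <- layerParamNames(layer)
  if (!is.null(nms) && !is.null(layer$grads)) {
    for (nm in nms) {
      g <- layer$grads[[nm]]
      s <- st[[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      layer[[nm]] <- layer[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      st[[nm]] <- s
    }
    layer$grads <- NULL
  }
  list(layer = layer, st = st)
}

adamInit <- function(net) lapply(net$layers, adamInitLayer)

adamStep <- function(net, opt, lr, t) {
  for (i in seq_along(net$layers)) {
    r <- adamStepLayer(net$layers[[i]], opt[[i]], lr, t)
    net$layers[[i]] <- r$layer
    opt[i] <- list(r$st)               # keep NULL states in place
  }
  list(net = net, opt = opt)
}

netParamCount <- function(net) {
  cnt <- function(layer) {
    if (layer$type == "residual")
      return(sum(vapply(layer$sub, cnt, numeric(1))))
    nms <- layerParamNames(layer)
    if (is.null(nms)) return(0)
    sum(vapply(nms, function(nm) length(layer[[nm]]), numeric(1)))
  }
  sum(vapply(net$layers, cnt, numeric(1)))
}

## --- prediction / evaluation helpers ---------------------------------------

## Forward a set of sample indices in evaluation mode, in chunks, returning
## the logit matrix.
netLogits <- function(net, makeBatch, idx, batchSize = 32L) {
  out <- NULL
  for (chunk in split(idx, ceiling(seq_along(idx) / batchSize))) {
    lo <- netForward(net, makeBatch(chunk), training = FALSE)$out
    out <- rbind(out, lo)
  }
  out
}

netEvalLossAcc <- function(net, makeBatch, labels, idx, batchSize = 32L) {
  lo <- netLogits(net, makeBatch, idx, batchSize)
  ce <- softmaxCrossEntropy(lo, labels[idx])
  pred <- max.col(ce$probs, ties.method = "first")
  list(loss = ce$loss, acc = mean(pred == labels[idx]))
}

## --- training loop ----------------------------------------------------------

## makeBatch(indices) must return the stacked network input for those
## acquisition indices; labels are integer class codes. Keeps the
## best-validation-accuracy parameters when valIdx is non-empty.
nnTrainLoop <- function(net, makeBatch, labels, trainIdx, valIdx = integer(0),
                        epochs = 10L, batchSize = 32L, lr = 1e-3,
                        seed = NULL, verbose = FALSE) {
  withSeed(seed, {
    opt <- adamInit(net)
    tstep <- 0L
    bestNet <- net
    bestAcc <- -Inf
    bestLoss <- Inf
    hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                       valLoss = numeric(0), valAcc = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample(trainIdx)
      chunks <- split(ord, ceiling(seq_along(ord) / batchSize))
      epLoss <- 0
      for (ch in chunks) {
        x <- makeBatch(ch)
        fw <- netForward(net, x, training = TRUE)
        net <- fw$net
        ce <- softmaxCrossEntropy(fw$out, labels[ch])
        net <- netBackward(net, ce$grad)
        tstep <- tstep + 1L
        up <- adamStep(net, opt, lr, tstep)
        net <- up$net
        opt <- up$opt
        epLoss <- epLoss + ce$loss * length(ch)
      }
      epLoss <- epLoss / length(ord)
      if (length(valIdx)) {
        ev <- netEvalLossAcc(net, makeBatch, labels, valIdx, batchSize)
        ## checkpoint on validation accuracy, ties broken by validation
        ## loss (a saturating accuracy would otherwise freeze the model
        ## at its first lucky epoch)
        if (ev$acc > bestAcc || (ev$acc == bestAcc && ev$loss < bestLoss)) {
          bestAcc <- ev$acc
          bestLoss <- ev$loss
          bestNet <- net
        }
        hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epLoss,
                                       valLoss = ev$loss, valAcc = ev$acc))
      } else {
        bestNet <- net
        hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epLoss,
                                       valLoss = NA_real_, valAcc = NA_real_))
      }
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f%s", ep, epLoss,
                        if (length(valIdx))
                          sprintf(", val loss %.4f, val acc %.3f",
                                  hist$valLoss[ep], hist$valAcc[ep]) else ""))
    }
    list(net = bestNet, finalNet = net, history = hist)
  })
}
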