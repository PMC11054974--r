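#' @include features.R
NULL

## ---------------------------------------------------------------------------
## Feature splicing
## ---------------------------------------------------------------------------

checkFuseDims <- function(m, n, z, dims) {
  lens <- c(image = length(m), spectral = length(n), haptic = length(z))
  if (!is.null(dims)) {
    bad <- names(dims)[lens != dims]
    if (length(bad))
      stop("feature dimension mismatch for modality ",
           paste(bad, collapse = ", "), ": got ",
           paste(lens[bad], collapse = ", "), ", expected ",
           paste(dims[bad], collapse = ", "))
  }
  lens
}

#' @rdname fuseFeatures
#' @param checkDims optional named integer vector of expected segment
#'   lengths (`c(image =, spectral =, haptic =)`, e.g. the printed
#'   8192/10/64); NULL (the default) accepts any widths, so reduced-width
#'   extractor configurations fuse too. The segment lengths are always
#'   recorded on the result.
setMethod("fuseFeatures",
  signature(m = "FeatureVector", n = "FeatureVector", z = "FeatureVector"),
  function(m, n, z, checkDims = NULL, ...) {
    for (fv in list(m, n, z))
      if (!is(fv, "FeatureVector"))
        stop("fuseFeatures expects three FeatureVector objects")
    mods <- c(featureModality(m), featureModality(n), featureModality(z))
    if (!identical(mods, c("image", "spectral", "haptic")))
      stop("fuseFeatures expects modalities in the order image, spectral, ",
           "haptic; got ", paste(mods, collapse = ", "))
    prov <- unique(stats::na.omit(c(m@fruitId, n@fruitId, z@fruitId)))
    if (length(prov) > 1L)
      stop("provenance mismatch: features come from fruits ",
           paste(prov, collapse = ", "))
    rots <- unique(stats::na.omit(c(m@rotation, n@rotation, z@rotation)))
    if (length(rots) > 1L)
      stop("provenance mismatch: features come from rotations ",
           paste(rots, collapse = ", "))
    lens <- checkFuseDims(m@values, n@values, z@values, checkDims)
    new("FusedFeature",
        values = c(m@values, n@values, z@values),
        segmentDims = stats::setNames(as.integer(lens),
                                      c("image", "spectral", "haptic")),
        fruitId = if (length(prov)) prov else NA_character_,
        rotation = if (length(rots)) as.integer(rots) else NA_integer_)
  })

#' @rdname fuseFeatures
setMethod("fuseFeatures",
  signature(m = "matrix", n = "matrix", z = "matrix"),
  function(m, n, z, checkDims = NULL, ...) {
    if (nrow(m) != nrow(n) || nrow(n) != nrow(z))
      stop("feature matrices must have one row per acquisition; got ",
           nrow(m), "/", nrow(n), "/", nrow(z), " rows")
    lens <- checkFuseDims(m[1, ], n[1, ], z[1, ], checkDims)
    out <- cbind(m, n, z)
    attr(out, "segmentDims") <- stats::setNames(
      as.integer(lens), c("image", "spectral", "haptic"))
    out
  })

## ---------------------------------------------------------------------------
## Fusion network
## ---------------------------------------------------------------------------

#' Configuration of the fused residual classifier
#'
#' The printed architecture: four fully connected layers of 8266, 512, 512
#' and 256 neurons (the first being the spliced input), each followed by
#' batch normalisation, ReLU and dropout, with a residual block of two
#' 512-wide fully connected layers (each followed by batch normalisation
#' and dropout, identity skip added before the activation) between the
#' second and third layers, and a final linear layer to the class logits.
#'
#' @param inputDim spliced feature length (8266 at default extractor
#'   widths).
#' @param widths the three hidden widths (512, 512, 256).
#' @param residualWidth width of the residual branch layers (must equal
#'   `widths[2]` for the identity skip).
#' @param dropout dropout rate after each normalised activation.
#' @param nClasses output classes.
#' @param lr,batchSize,epochs,seed training hyperparameters.
#' @return A named configuration list.
#' @export
fusionNetConfig <- function(inputDim = 8266L, widths = c(512L, 512L, 256L),
                            residualWidth = widths[2], dropout = 0.5,
                            nClasses = 3L, lr = 1e-3, batchSize = 32L,
                            epochs = 50L, seed = 1L) {
  if (residualWidth != widths[2])
    stop("residual width ", residualWidth, " is incompatible with the ",
         "identity skip around the ", widths[2], "-wide second layer")
  list(inputDim = as.integer(inputDim), widths = as.integer(widths),
       residualWidth = as.integer(residualWidth), dropout = dropout,
       nClasses = as.integer(nClasses), lr = lr,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       seed = as.integer(seed))
}

#' Build the fused fully connected residual network
#'
#' @param config from [fusionNetConfig()].
#' @param classes class labels in logit order (default the three maturity
#'   stages).
#' @return An untrained [FusionClassifier-class].
#' @examples
#' net <- buildFusionNetwork(fusionNetConfig(inputDim = 100))
#' @export
buildFusionNetwork <- function(config = fusionNetConfig(),
                               classes = maturityStages()) {
  if (length(classes) != config$nClasses)
    stop("classes must match config$nClasses")
  withSeed(config$seed, {
    w <- config$widths
    p <- config$dropout
    layers <- list(
      initLinear(config$inputDim, w[1]), initBatchNorm(w[1]), initRelu(),
      initDropout(p),
      initLinear(w[1], w[2]), initBatchNorm(w[2]), initRelu(),
      initDropout(p),
      initResidual(list(
        initLinear(w[2], config$residualWidth),
        initBatchNorm(config$residualWidth), initDropout(p),
        initLinear(config$residualWidth, w[2]),
        initBatchNorm(w[2]), initDropout(p))),
      initRelu(),                        # activation after the skip addition
      initLinear(w[2], w[3]), initBatchNorm(w[3]), initRelu(),
      initDropout(p),
      initLinear(w[3], config$nClasses))
    net <- list(layers = layers, tap = NULL)
    cfg <- config
    cfg$nParams <- netParamCount(net)
    new("FusionClassifier", net = net, config = cfg, classes = classes)
  })
}

## ---------------------------------------------------------------------------
## Split protocol
## ---------------------------------------------------------------------------

#' Stratified fruit-level train/validation/test split
#'
#' Assigns whole fruits (all rotations together, so no rotation leakage)
#' to train/validation/test with fractions 64/16/20 by default, stratified
#' by label with largest-remainder apportionment inside each class;
#' deterministic for a fixed seed.
#'
#' @param manifest a [PhantomManifest-class] (or a data.frame with
#'   `fruit_id` and `label` columns).
#' @param fractions length-3 fractions summing to 1 (within 1e-6).
#' @param seed split seed.
#' @return A [DatasetSplit-class].
#' @examples
#' m <- generateManifest(10, 10, 10, seed = 1)
#' makeSplit(m, seed = 1)
#' @export
makeSplit <- function(manifest, fractions = c(0.64, 0.16, 0.20), seed = 1L) {
  if (is(manifest, "PhantomManifest"))
    fruits <- unique(manifest@records[, c("fruit_id", "label")])
  else
    fruits <- unique(manifest[, c("fruit_id", "label")])
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("split fractions must sum to 1")
  withSeed(seed, {
    tr <- va <- te <- character(0)
    for (lab in unique(fruits$label)) {
      ids <- sample(fruits$fruit_id[fruits$label == lab])
      nPer <- apportion(length(ids), fractions)
      if (any(nPer == 0L))
        stop("class ", lab, " has too few fruits (", length(ids),
             ") to populate all three splits")
      tr <- c(tr, ids[seq_len(nPer[1])])
      va <- c(va, ids[nPer[1] + seq_len(nPer[2])])
      te <- c(te, ids[nPer[1] + nPer[2] + seq_len(nPer[3])])
    }
    new("DatasetSplit", trainIds = tr, valIds = va, testIds = te,
        fractions = fractions, seed = as.numeric(seed))
  })
}

## ---------------------------------------------------------------------------
## Fusion training and prediction
## ---------------------------------------------------------------------------

#' Train the fused classifier on cached spliced features
#'
#' Two-stage protocol: the unimodal extractors are trained first and
#' frozen; this function trains only the fused residual network on the
#' precomputed spliced features, with softmax cross-entropy and Adam,
#' logging train/validation loss per epoch and returning the parameters of
#' the best-validation-accuracy epoch.
#'
#' @param model an untrained [FusionClassifier-class] whose `inputDim`
#'   matches `ncol(fused)`.
#' @param fused matrix of spliced features, one acquisition per row.
#' @param labels character labels, one per row.
#' @param fruitIds fruit id per row (used with `split`).
#' @param split a [DatasetSplit-class]; NULL trains on everything.
#' @param epochs,batchSize,lr,seed overrides of the config values.
#' @return The trained model with `@history` and per-split `@metrics`.
#' @export
trainFusion <- function(model, fused, labels, fruitIds = NULL, split = NULL,
                        epochs = model@config$epochs,
                        batchSize = model@config$batchSize,
                        lr = model@config$lr, seed = model@config$seed) {
  stopifnot(is(model, "FusionClassifier"))
  if (nrow(fused) != length(labels))
    stop("fused features and labels must agree: ", nrow(fused), " rows vs ",
         length(labels), " labels")
  if (ncol(fused) != model@config$inputDim)
    stop("fused feature length ", ncol(fused), " does not match the ",
         "network input dimension ", model@config$inputDim)
  classes <- model@classes
  if (!all(labels %in% classes))
    stop("labels outside the model's classes: ",
         paste(setdiff(labels, classes), collapse = ", "))
  y <- match(labels, classes)
  idx <- splitIndices(split, fruitIds, nrow(fused))
  if (length(unique(y[idx$train])) < 2L)
    stop("training set contains a single class; cannot train a classifier")
  makeBatch <- function(ii) fused[ii, , drop = FALSE]
  res <- nnTrainLoop(model@net, makeBatch, y, idx$train, idx$validation,
                     epochs = epochs, batchSize = batchSize, lr = lr,
                     seed = seed)
  model@net <- res$net
  model@history <- res$history
  model@trained <- TRUE
  model@metrics <- lapply(idx, function(ii) {
    if (!length(ii)) return(NULL)
    lo <- netLogits(model@net, makeBatch, ii, batchSize)
    pred <- classes[max.col(lo, ties.method = "first")]
    evaluatePredictions(labels[ii], pred, classes)
  })
  model
}

#' @rdname predictMaturity
setMethod("predictMaturity", "FusionClassifier", function(object, features,
                                                          ...) {
  x <- if (is(features, "FusedFeature"))
    matrix(featureValues(features), 1)
  else if (is.matrix(features)) features
  else matrix(as.numeric(features), 1)
  if (ncol(x) != object@config$inputDim)
    stop("fused feature length ", ncol(x), " does not match the network ",
         "input dimension ", object@config$inputDim)
  lo <- netForward(object@net, x, training = FALSE)$out
  probs <- softmaxProbs(lo)
  colnames(probs) <- object@classes
  labels <- object@classes[max.col(probs, ties.method = "first")]
  list(label = labels, probabilities = probs)
})

## ---------------------------------------------------------------------------
## Linear probe (single linear layer) used for unimodal baselines on
## frozen features, e.g. the image-only heterogeneous baseline.
## ---------------------------------------------------------------------------

trainLinearProbe <- function(features, labels, classes, trainIdx,
                             epochs = 60L, lr = 1e-2, batchSize = 32L,
                             seed = 1L) {
  y <- match(labels, classes)
  net <- withSeed(seed,
                  list(layers = list(initLinear(ncol(features),
                                                length(classes))),
                       tap = NULL))
  makeBatch <- function(ii) features[ii, , drop = FALSE]
  res <- nnTrainLoop(net, makeBatch, y, trainIdx, integer(0),
                     epochs = epochs, batchSize = batchSize, lr = lr,
                     seed = seed)
  list(net = res$net, classes = classes,
       predict = function(idx) {
         lo <- netLogits(res$net, makeBatch, idx, batchSize)
         classes[max.col(lo, ties.method = "first")]
       })
}
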