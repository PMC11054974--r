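#' @include nn-network.R preprocess.R
NULL

## ---------------------------------------------------------------------------
## Extractor configurations
## ---------------------------------------------------------------------------

vggChannels <- c(64L, 128L, 256L, 512L, 512L)
vggBlocks <- c(2L, 2L, 3L, 3L, 3L)

#' Extractor configurations
#'
#' Build the configuration lists for the three unimodal extractors. The
#' defaults reproduce the printed feature dimensionalities exactly: the
#' image extractor is a VGG16-style stack (five convolutional blocks of
#' 2/2/3/3/3 3x3 convolutions, each block ending in a stride-2 max pool)
#' whose flattened final pooled output on a 150 x 150 input is
#' 4 x 4 x 512 = 8192; the spectral extractor is a 1-D CNN of three
#' convolution blocks (kernel 7/5/3, channels 16/32/10, each followed by
#' batch normalisation, ReLU and a stride-2 max pool) with global max
#' pooling to a 10-vector; the haptic extractor is a single-layer LSTM with
#' hidden size 64 whose final hidden state is the 64-vector tap. Any
#' deviation from the printed architecture (width scale, block depths,
#' batch-norm in the image stack, haptic input stride) flags the
#' configuration as non-paper; it remains fully functional.
#'
#' @param widthScale multiplier on the image channel widths (1 = printed
#'   architecture; 1/8 gives a 1024-length tap).
#' @param layersPerBlock convolutions per image block.
#' @param inputSize expected segmented image side (150).
#' @param batchNorm add batch normalisation after image convolutions
#'   (non-paper; speeds up small-budget training).
#' @param headWidths fully connected head widths above the feature tap.
#' @param hidden LSTM hidden size (64).
#' @param stride haptic input downsampling stride (1 = use every sample).
#' @param inputLength expected spectral grid length (default 751).
#' @param channels,kernels spectral convolution channels and kernel sizes.
#' @param hiddenUnits spectral classification-head hidden width.
#' @param dropout head dropout rate.
#' @param lr,batchSize,epochs,seed training hyperparameters.
#' @return A named configuration list.
#' @name extractorConfig
NULL

#' @rdname extractorConfig
#' @export
imageExtractorConfig <- function(widthScale = 1,
                                 layersPerBlock = vggBlocks,
                                 inputSize = 150L, batchNorm = FALSE,
                                 headWidths = c(256L, 64L), dropout = 0.5,
                                 lr = 1e-3, batchSize = 32L, epochs = 50L,
                                 seed = 1L) {
  channels <- as.integer(round(vggChannels * widthScale))
  if (any(channels < 1))
    stop("widthScale too small: a block would have zero channels")
  s <- inputSize
  for (i in 1:5) s <- s %/% 2L
  featureDim <- as.integer(s * s * channels[5])
  paperConfig <- widthScale == 1 && identical(as.integer(layersPerBlock),
                                              vggBlocks) &&
    inputSize == 150L && !batchNorm
  if (widthScale == 1 && featureDim != 8192L)
    stop("input size ", inputSize, " yields a pooled feature length of ",
         featureDim, " at full width; the printed architecture requires ",
         "8192 (input 150)")
  list(modality = "image", widthScale = widthScale, channels = channels,
       layersPerBlock = as.integer(layersPerBlock), inputSize = inputSize,
       batchNorm = batchNorm, headWidths = as.integer(headWidths),
       dropout = dropout, lr = lr, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), seed = as.integer(seed),
       featureDim = featureDim, finalSpatial = s,
       paperConfig = paperConfig)
}

#' @rdname extractorConfig
#' @export
spectralCNNConfig <- function(inputLength = 751L,
                              channels = c(16L, 32L, 10L),
                              kernels = c(7L, 5L, 3L), hiddenUnits = 16L,
                              dropout = 0.5, lr = 1e-3, batchSize = 32L,
                              epochs = 50L, seed = 1L) {
  if (length(channels) != 3L || length(kernels) != 3L)
    stop("the spectral extractor has exactly three convolution blocks")
  paperConfig <- channels[3] == 10L
  list(modality = "spectral", inputLength = as.integer(inputLength),
       channels = as.integer(channels), kernels = as.integer(kernels),
       hiddenUnits = as.integer(hiddenUnits), dropout = dropout, lr = lr,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       seed = as.integer(seed), featureDim = as.integer(channels[3]),
       minLength = 8L, paperConfig = paperConfig)
}

#' @rdname extractorConfig
#' @export
hapticLSTMConfig <- function(hidden = 64L, stride = 1L, dropout = 0,
                             lr = 1e-3, batchSize = 32L, epochs = 50L,
                             seed = 1L, scale = 50) {
  list(modality = "haptic", hidden = as.integer(hidden),
       stride = as.integer(stride), dropout = dropout, lr = lr,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       seed = as.integer(seed), featureDim = as.integer(hidden),
       scale = scale, paperConfig = stride == 1L && hidden == 64L)
}

## ---------------------------------------------------------------------------
## Builders
## ---------------------------------------------------------------------------

#' Build the unimodal extractors
#'
#' Each builder initialises the network (seeded by `config$seed`), marks
#' the feature-tap layer, and attaches a classification head (three fully
#' connected layers for the image model, two linear layers for the spectral
#' model, one linear layer for the haptic model) used for unimodal
#' training; [extractFeatures()] reads the tap, ignoring the head.
#'
#' @param config from [imageExtractorConfig()], [spectralCNNConfig()] or
#'   [hapticLSTMConfig()].
#' @param nClasses classification-head output classes (default 3 stages).
#' @return A [ModalityExtractor-class].
#' @examples
#' ext <- buildSpectralCNN()
#' featureDim(ext)  # 10
#' @name buildExtractor
NULL

#' @rdname buildExtractor
#' @export
buildImageExtractor <- function(config = imageExtractorConfig(),
                                nClasses = 3L) {
  withSeed(config$seed, {
    layers <- list()
    cin <- 3L
    first <- TRUE
    for (b in 1:5) {
      for (l in seq_len(config$layersPerBlock[b])) {
        layers <- c(layers, list(initConv2d(3L, cin, config$channels[b],
                                            first = first)))
        first <- FALSE
        if (config$batchNorm)
          layers <- c(layers, list(initBatchNorm(config$channels[b],
                                                 kind = "conv2d")))
        layers <- c(layers, list(initRelu()))
        cin <- config$channels[b]
      }
      layers <- c(layers, list(initMaxPool2d()))
    }
    layers <- c(layers, list(initFlatten()))
    tap <- length(layers)
    din <- config$featureDim
    for (w in config$headWidths) {
      layers <- c(layers, list(initLinear(din, w), initRelu(),
                               initDropout(config$dropout)))
      din <- w
    }
    layers <- c(layers, list(initLinear(din, nClasses)))
    net <- list(layers = layers, tap = tap)
    new("ModalityExtractor", modality = "image", net = net, config = config)
  })
}

#' @rdname buildExtractor
#' @export
buildSpectralCNN <- function(config = spectralCNNConfig(), nClasses = 3L) {
  if (config$inputLength < config$minLength)
    stop("spectral grid length ", config$inputLength,
         " is shorter than the receptive field of the three pooled blocks (",
         config$minLength, ")")
  withSeed(config$seed, {
    layers <- list()
    cin <- 1L
    for (b in 1:3) {
      layers <- c(layers, list(
        initConv1d(config$kernels[b], cin, config$channels[b],
                   first = b == 1L),
        initBatchNorm(config$channels[b], kind = "conv1d"),
        initRelu(), initMaxPool1d()))
      cin <- config$channels[b]
    }
    layers <- c(layers, list(initGlobalMaxPool1d()))
    tap <- length(layers)
    layers <- c(layers, list(initLinear(config$featureDim,
                                        config$hiddenUnits),
                             initRelu(),
                             initLinear(config$hiddenUnits, nClasses)))
    net <- list(layers = layers, tap = tap)
    new("ModalityExtractor", modality = "spectral", net = net,
        config = config)
  })
}

#' @rdname buildExtractor
#' @export
buildHapticLSTM <- function(config = hapticLSTMConfig(), nClasses = 3L) {
  withSeed(config$seed, {
    layers <- list(initLSTM(1L, config$hidden))
    tap <- 1L
    layers <- c(layers, list(initLinear(config$hidden, nClasses)))
    net <- list(layers = layers, tap = tap)
    new("ModalityExtractor", modality = "haptic", net = net,
        config = config)
  })
}

## ---------------------------------------------------------------------------
## Input stacking
## ---------------------------------------------------------------------------

## Normalise a single image input to the network scale.
imageInput <- function(x, config) {
  if (is(x, "SegmentedImage")) x <- imagePixels(x)
  d <- dim(x)
  if (length(d) != 3L || d[1] != config$inputSize || d[2] != config$inputSize)
    stop("image must be preprocessed to ", config$inputSize, " x ",
         config$inputSize, " x 3 (got ", paste(d, collapse = "x"), ")")
  x / 255 - 0.5
}

spectralInput <- function(x, config) {
  if (is(x, "Spectrum")) x <- correctedSignal(x)
  as.numeric(x)
}

hapticInput <- function(x, config) {
  if (is(x, "HapticTrace")) x <- pressure(x)
  if (!length(x))
    stop("empty haptic trace")
  x <- as.numeric(x)
  if (config$stride > 1L)
    x <- x[seq(1L, length(x), by = config$stride)]
  x / config$scale
}

## Stack a list of per-acquisition inputs into the network batch shape.
stackBatch <- function(model, xs) {
  cfg <- model@config
  switch(model@modality,
    image = {
      xs <- lapply(xs, imageInput, config = cfg)
      array(unlist(xs, use.names = FALSE),
            c(cfg$inputSize, cfg$inputSize, 3L, length(xs)))
    },
    spectral = {
      xs <- lapply(xs, spectralInput, config = cfg)
      L <- unique(lengths(xs))
      if (length(L) != 1L)
        stop("spectra in a batch must share a grid length")
      if (L < cfg$minLength)
        stop("spectral grid length ", L, " is shorter than the receptive ",
             "field of the three pooled blocks (", cfg$minLength, ")")
      array(unlist(xs, use.names = FALSE), c(L, 1L, length(xs)))
    },
    haptic = {
      xs <- lapply(xs, hapticInput, config = cfg)
      L <- unique(lengths(xs))
      if (length(L) != 1L)
        stop("haptic traces in a batch must share a length")
      arr <- array(0, c(L, 1L, length(xs)))
      arr[, 1L, ] <- matrix(unlist(xs, use.names = FALSE), L)
      arr
    })
}

asInputList <- function(model, x) {
  if (is.list(x) && !isS4(x)) return(x)
  if (model@modality == "image") {
    d <- dim(x)
    if (!is.null(d) && length(d) == 4L)
      return(lapply(seq_len(d[4]), function(i) x[, , , i]))
    return(list(x))
  }
  if (is.matrix(x))
    return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  list(x)
}

## ---------------------------------------------------------------------------
## Feature extraction
## ---------------------------------------------------------------------------

#' @rdname extractFeatures
#' @param fruitId,rotation optional provenance recorded on a single-input
#'   result.
#' @param batchSize evaluation chunk size for batch inputs.
setMethod("extractFeatures", "ModalityExtractor",
  function(object, x, fruitId = NA_character_, rotation = NA_integer_,
           batchSize = 32L, ...) {
    single <- !(is.list(x) && !isS4(x)) &&
      !(object@modality == "image" && length(dim(x)) == 4L) &&
      !(object@modality != "image" && is.matrix(x))
    xs <- asInputList(object, x)
    out <- NULL
    for (chunk in split(seq_along(xs),
                        ceiling(seq_along(xs) / batchSize))) {
      fb <- netFeatures(object@net, stackBatch(object, xs[chunk]))
      out <- rbind(out, fb)
    }
    if (single)
      return(FeatureVector(object@modality, out[1, ], fruitId = fruitId,
                           rotation = as.integer(rotation)))
    rownames(out) <- NULL
    out
  })

## ---------------------------------------------------------------------------
## Unimodal training
## ---------------------------------------------------------------------------

#' Train a unimodal classifier on one modality
#'
#' Trains the extractor end to end (feature stack plus classification head)
#' with softmax cross-entropy and Adam on the training fruits of the split,
#' logging the loss per epoch, checkpointing the best-validation-accuracy
#' epoch, and reporting accuracy/precision/recall on all three splits.
#'
#' @param model a [ModalityExtractor-class].
#' @param inputs list of per-acquisition preprocessed inputs
#'   ([SegmentedImage-class] / corrected [Spectrum-class] / filtered
#'   [HapticTrace-class], or bare arrays/vectors).
#' @param labels character class labels, one per acquisition.
#' @param fruitIds fruit id per acquisition (used with `split`).
#' @param split a [DatasetSplit-class]; NULL trains on everything.
#' @param epochs,batchSize,lr overrides of the config values.
#' @param seed training seed (default from the config).
#' @return The trained model, with `@history` (per-epoch losses) and
#'   `@metrics` (a [MetricsReport][evaluatePredictions()] per split)
#'   populated.
#' @export
trainUnimodal <- function(model, inputs, labels, fruitIds = NULL,
                          split = NULL, epochs = model@config$epochs,
                          batchSize = model@config$batchSize,
                          lr = model@config$lr,
                          seed = model@config$seed) {
  stopifnot(is(model, "ModalityExtractor"))
  if (length(labels) != length(inputs))
    stop("labels and inputs must have equal length")
  classes <- intersect(allLabels(), unique(labels))
  y <- match(labels, classes)
  idx <- splitIndices(split, fruitIds, length(inputs))
  if (length(unique(y[idx$train])) < 2L)
    stop("training set contains a single class; cannot train a classifier")
  makeBatch <- function(ii) stackBatch(model, inputs[ii])
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

## Train/validation/test acquisition indices from a fruit-level split.
splitIndices <- function(split, fruitIds, n) {
  if (is.null(split))
    return(list(train = seq_len(n), validation = integer(0),
                test = integer(0)))
  if (is.null(fruitIds))
    stop("fruitIds are required when a split is given")
  list(train = which(fruitIds %in% split@trainIds),
       validation = which(fruitIds %in% split@valIds),
       test = which(fruitIds %in% split@testIds))
}
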