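# Extractor tests run at reduced image width where the contract allows it;
# the full-width 8192 tap is exercised in the acceptance suite.

deskImage <- function(seed = 1L)
  buildImageExtractor(imageExtractorConfig(widthScale = 1 / 16,
                                           layersPerBlock = rep(1L, 5L),
                                           batchNorm = TRUE,
                                           headWidths = 32L, seed = seed))

test_that("feature taps have the architecture-forced lengths", {
  spec <- buildSpectralCNN()
  sp <- correctSpectrum(synthesizeSpectrum("mature", seed = 1))
  expect_equal(featureDim(extractFeatures(spec, sp)), 10)
  # global max pooling makes the tap length grid-independent
  expect_equal(featureDim(extractFeatures(spec, rep(0.5, 400))), 10)
  zero <- extractFeatures(spec, rep(0, 751))
  expect_true(all(is.finite(featureValues(zero))))

  lstm <- buildHapticLSTM()
  tr <- butterworthLowpass(synthesizeHapticTrace("mature", seed = 2))
  expect_equal(featureDim(extractFeatures(lstm, tr)), 64)
  expect_equal(featureDim(extractFeatures(lstm, pressure(tr)[1:750])), 64)
  z1 <- extractFeatures(lstm, rep(0, 1500))
  z2 <- extractFeatures(lstm, rep(0, 1500))
  expect_identical(featureValues(z1), featureValues(z2))

  # reduced-width image stack: 1/8 channels -> 4 x 4 x 64 = 1024, flagged
  cfg8 <- imageExtractorConfig(widthScale = 1 / 8)
  expect_equal(cfg8$featureDim, 1024)
  expect_false(cfg8$paperConfig)

  ext <- deskImage()
  seg <- segmentImage(renderTomatoImage("mature", seed = 3))
  fv <- extractFeatures(ext, seg)
  expect_equal(featureDim(fv), ext@config$featureDim)
  expect_true(all(is.finite(featureValues(fv))))

  # batch of k inputs gives a k x dim matrix
  segs <- lapply(4:6, function(s)
    segmentImage(renderTomatoImage("immature", seed = s)))
  fm <- extractFeatures(ext, segs)
  expect_equal(dim(fm), c(3L, ext@config$featureDim))
})

test_that("feature extraction is deterministic in evaluation mode", {
  ext <- deskImage()
  seg <- segmentImage(renderTomatoImage("semi_mature", seed = 7))
  expect_identical(featureValues(extractFeatures(ext, seg)),
                   featureValues(extractFeatures(ext, seg)))
  spec <- buildSpectralCNN()
  sp <- correctSpectrum(synthesizeSpectrum("immature", seed = 8))
  expect_identical(featureValues(extractFeatures(spec, sp)),
                   featureValues(extractFeatures(spec, sp)))
})

test_that("invalid inputs and configurations are rejected with clear errors", {
  # full-width architecture demands the 150-pixel input (8192 tap)
  expect_error(imageExtractorConfig(inputSize = 100), "4608")
  expect_error(imageExtractorConfig(widthScale = 1 / 200), "zero channels")
  # unpreprocessed image size
  ext <- deskImage()
  expect_error(extractFeatures(ext, array(0, c(100, 100, 3))),
               "150 x 150")
  # spectral grid shorter than the pooled receptive field
  expect_error(buildSpectralCNN(spectralCNNConfig(inputLength = 4)),
               "shorter")
  spec <- buildSpectralCNN()
  expect_error(extractFeatures(spec, rep(0, 4)), "shorter")
  # empty haptic trace
  lstm <- buildHapticLSTM()
  expect_error(extractFeatures(lstm, numeric(0)), "empty")
})

test_that("unimodal training learns separable haptic phantoms", {
  labels <- rep(maturityStages(), each = 8)
  traces <- lapply(seq_along(labels), function(i)
    butterworthLowpass(synthesizeHapticTrace(labels[i], seed = 500 + i)))
  fruitIds <- sprintf("F%04d", seq_along(labels))
  manifest <- data.frame(fruit_id = fruitIds, label = labels)
  split <- makeSplit(manifest, seed = 1)

  cfg <- hapticLSTMConfig(stride = 10L, epochs = 25L, seed = 2L)
  model <- trainUnimodal(buildHapticLSTM(cfg), traces, labels, fruitIds,
                         split)
  expect_true(model@trained)
  expect_gt(model@metrics$test$accuracy, 1 / 3)      # above chance
  expect_lt(model@history$trainLoss[nrow(model@history)],
            model@history$trainLoss[1])

  # permutation null: shuffled labels stay near chance on held-out fruits
  shuffled <- withr::with_seed(9, sample(labels))
  nullModel <- suppressWarnings(
    trainUnimodal(buildHapticLSTM(cfg), traces, shuffled, fruitIds, split))
  expect_lte(nullModel@metrics$test$accuracy, 0.75)

  # a single-class training set is rejected
  expect_error(trainUnimodal(buildHapticLSTM(cfg), traces,
                             rep("mature", length(traces))),
               "single class")
})
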