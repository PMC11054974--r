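#' @include evaluation.R
NULL

#' Experiment configuration presets
#'
#' Bundles every knob of the end-to-end experiments. Two presets exist:
#' \describe{
#'   \item{paper}{every printed dimension: 79/60/75 fruits x 4 rotations,
#'     full-width VGG16-style image extractor (8192-dim tap), full-rate
#'     LSTM input, spliced length 8266. Intended for dimension-contract
#'     checks and full-scale runs.}
#'   \item{desk}{a small-footprint configuration used by the bundled
#'     experiments and tests: 24 fruits per stage, reduced-width image
#'     stack (one convolution per block, 1/16 channel width, batch
#'     normalisation) giving a 512-dim tap, haptic input stride 10, and
#'     short training budgets. The spliced layout contract (image |
#'     spectral | haptic, length = sum of the taps) is unchanged.}
#' }
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param counts fruits per maturity stage (length 3).
#' @param nRotations acquisitions per fruit and device.
#' @param heteroTrainCounts,heteroValCounts fruits per heterogeneity
#'   category for the heterogeneous experiment (training and validation).
#' @param fractions split fractions.
#' @param outDir optional directory for run artifacts (reports, loss
#'   curves, run manifest); NULL keeps everything in memory.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(preset = c("desk", "paper"), seed = 1L,
                      counts = NULL, nRotations = 4L,
                      heteroTrainCounts = c(12L, 12L, 12L),
                      heteroValCounts = c(6L, 6L, 6L),
                      fractions = c(0.64, 0.16, 0.20), outDir = NULL) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  if (is.null(counts))
    counts <- if (preset == "paper") c(79L, 60L, 75L) else c(24L, 24L, 24L)
  if (preset == "paper") {
    imageCfg <- imageExtractorConfig(seed = seed + 2L)
    spectralCfg <- spectralCNNConfig(seed = seed + 3L)
    hapticCfg <- hapticLSTMConfig(seed = seed + 4L)
    fusionEpochs <- 50L
  } else {
    imageCfg <- imageExtractorConfig(widthScale = 1 / 16,
                                     layersPerBlock = rep(1L, 5L),
                                     batchNorm = TRUE, headWidths = 64L,
                                     dropout = 0.25, epochs = 12L,
                                     seed = seed + 2L)
    spectralCfg <- spectralCNNConfig(epochs = 40L, seed = seed + 3L)
    hapticCfg <- hapticLSTMConfig(stride = 10L, epochs = 30L,
                                  seed = seed + 4L)
    fusionEpochs <- 60L
  }
  structure(list(preset = preset, seed = seed, counts = as.integer(counts),
                 nRotations = as.integer(nRotations),
                 heteroTrainCounts = as.integer(heteroTrainCounts),
                 heteroValCounts = as.integer(heteroValCounts),
                 fractions = fractions, phantom = phantomDefaults(),
                 image = imageCfg, spectral = spectralCfg,
                 haptic = hapticCfg, fusionEpochs = fusionEpochs,
                 outDir = outDir),
            class = c("RunConfig", "list"))
}

#' Read an experiment configuration from YAML
#'
#' Builds a [runConfig()] from a YAML file. Top-level keys `preset`,
#' `seed`, `counts`, `nRotations`, `heteroTrainCounts`, `heteroValCounts`,
#' `fractions` and `outDir` are passed to [runConfig()]; an optional
#' `phantom:` block overrides generator parameters (merged recursively
#' into [phantomDefaults()]), and optional `image:`/`spectral:`/`haptic:`
#' blocks override individual extractor settings (e.g. `epochs`).
#'
#' @param path YAML file path.
#' @return A `RunConfig` list.
#' @export
runConfigFromYAML <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("preset", "seed", "counts", "nRotations",
                                  "heteroTrainCounts", "heteroValCounts",
                                  "fractions", "outDir"))]
  cfg <- do.call(runConfig, args)
  if (!is.null(y$phantom))
    cfg$phantom <- modifyList(cfg$phantom, y$phantom)
  for (m in c("image", "spectral", "haptic"))
    if (!is.null(y[[m]]))
      cfg[[m]] <- modifyList(cfg[[m]], y[[m]])
  cfg
}

## Preprocess every acquisition of a manifest into extractor inputs.
## Returns parallel lists/vectors ordered fruit-major, rotation-minor.
preprocessManifest <- function(manifest, config) {
  samples <- generateDataset(manifest, config$phantom)
  n <- length(samples)
  images <- vector("list", n)
  spectra <- vector("list", n)
  traces <- vector("list", n)
  labels <- character(n)
  fruitIds <- character(n)
  rotations <- integer(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    pp <- preprocessSample(s, outSize = config$image$inputSize)
    px <- imagePixels(pp$image)
    storage.mode(px) <- "integer"      # halves the memory footprint
    images[[i]] <- px
    spectra[[i]] <- correctedSignal(pp$spectrum)
    traces[[i]] <- pressure(pp$haptic)
    labels[i] <- s@label
    fruitIds[i] <- s@fruitId
    rotations[i] <- s@rotation
  }
  list(images = images, spectra = spectra, traces = traces,
       labels = labels, fruitIds = fruitIds, rotations = rotations)
}

## Extract the three frozen feature matrices and splice them.
spliceAll <- function(extractors, data, batchSize = 32L) {
  m <- extractFeatures(extractors$image, data$images, batchSize = batchSize)
  n <- extractFeatures(extractors$spectral, data$spectra,
                       batchSize = batchSize)
  z <- extractFeatures(extractors$haptic, data$traces,
                       batchSize = batchSize)
  fuseFeatures(m, n, z)
}

#' Run the three-stage classification experiment
#'
#' The full unimodal-versus-fusion comparison on synthetic phantoms:
#' generates the dataset, preprocesses all three modalities, trains the
#' three unimodal classifiers and the fused residual network on a shared
#' fruit-level split, and reports accuracy/precision/recall for all four
#' models on train/validation/test. Fully determined by the config seed.
#'
#' @param config a [runConfig()] list.
#' @return List with the manifest, split, trained `extractors` and
#'   `fusion` model, the spliced `features`, per-acquisition `labels` and
#'   `fruitIds`, and `comparison` (test metrics of the four models).
#' @examples
#' \donttest{
#' res <- runStageExperiment(runConfig("desk", seed = 1,
#'                                     counts = c(6, 6, 6)))
#' res$comparison
#' }
#' @export
runStageExperiment <- function(config = runConfig()) {
  manifest <- generateManifest(config$counts[1], config$counts[2],
                               config$counts[3], config$nRotations,
                               seed = config$seed)
  data <- preprocessManifest(manifest, config)
  split <- makeSplit(manifest, config$fractions, seed = config$seed + 1L)
  extractors <- list(
    image = trainUnimodal(buildImageExtractor(config$image), data$images,
                          data$labels, data$fruitIds, split),
    spectral = trainUnimodal(buildSpectralCNN(config$spectral),
                             data$spectra, data$labels, data$fruitIds,
                             split),
    haptic = trainUnimodal(buildHapticLSTM(config$haptic), data$traces,
                           data$labels, data$fruitIds, split))
  fused <- spliceAll(extractors, data)
  fusionCfg <- fusionNetConfig(inputDim = ncol(fused),
                               epochs = config$fusionEpochs,
                               seed = config$seed + 5L)
  fusion <- trainFusion(buildFusionNetwork(fusionCfg), fused, data$labels,
                        data$fruitIds, split)
  comparison <- data.frame(
    model = c("image", "spectral", "haptic", "fusion"),
    testAccuracy = c(
      vapply(extractors, function(m) m@metrics$test$accuracy, numeric(1)),
      fusion@metrics$test$accuracy),
    testPrecision = c(
      vapply(extractors, function(m) m@metrics$test$macroPrecision,
             numeric(1)),
      fusion@metrics$test$macroPrecision),
    testRecall = c(
      vapply(extractors, function(m) m@metrics$test$macroRecall,
             numeric(1)),
      fusion@metrics$test$macroRecall),
    row.names = NULL)
  res <- list(manifest = manifest, split = split, extractors = extractors,
              fusion = fusion, features = fused, labels = data$labels,
              fruitIds = data$fruitIds, comparison = comparison,
              config = config)
  if (!is.null(config$outDir))
    writeRunArtifacts(res, config$outDir, "stage")
  res
}

#' Run the heterogeneous internal/external maturity experiment
#'
#' Fruits with a fully red exterior but different internal states
#' (negative sample 1, negative sample 2, positive) cannot be separated by
#' the image modality by design. This experiment freezes the stage-trained
#' extractors, trains a fresh fused residual head on heterogeneous-category
#' phantoms, and validates on an independent set (default 6 fruits per
#' category = 18 samples), alongside image-only and haptic-only linear
#' baselines on the same frozen features.
#'
#' @param config a [runConfig()] list.
#' @param extractors trained extractors from [runStageExperiment()]; when
#'   NULL a stage experiment is run first to obtain them.
#' @return List with the validation `report` ([evaluatePredictions()]),
#'   `imageOnly`/`hapticOnly` baseline reports, and the binary
#'   positive-versus-negative balanced accuracies (`posNegBalanced`).
#' @export
runHeterogeneousExperiment <- function(config = runConfig(),
                                       extractors = NULL) {
  if (is.null(extractors))
    extractors <- runStageExperiment(config)$extractors
  hc <- config$heteroTrainCounts
  vc <- config$heteroValCounts
  trainManifest <- generateManifest(0L, 0L, 0L, config$nRotations,
                                    seed = config$seed + 6L,
                                    heterogeneous = c(negative1 = hc[1],
                                                      negative2 = hc[2],
                                                      positive = hc[3]))
  valManifest <- generateManifest(0L, 0L, 0L, 1L,
                                  seed = config$seed + 7L,
                                  heterogeneous = c(negative1 = vc[1],
                                                    negative2 = vc[2],
                                                    positive = vc[3]))
  trainData <- preprocessManifest(trainManifest, config)
  valData <- preprocessManifest(valManifest, config)
  trainFused <- spliceAll(extractors, trainData)
  valFused <- spliceAll(extractors, valData)
  classes <- heterogeneityCategories()
  fusionCfg <- fusionNetConfig(inputDim = ncol(trainFused),
                               epochs = config$fusionEpochs,
                               seed = config$seed + 8L)
  fusion <- trainFusion(buildFusionNetwork(fusionCfg, classes = classes),
                        trainFused, trainData$labels)
  pred <- predictMaturity(fusion, valFused)$label
  report <- evaluatePredictions(valData$labels, pred, classes)

  ## unimodal baselines: linear heads over the frozen per-modality features
  nTr <- nrow(trainFused)
  seg <- attr(trainFused, "segmentDims")
  ends <- cumsum(seg)
  starts <- c(1L, ends[-3] + 1L)
  baseline <- function(k, seedOff) {
    trF <- trainFused[, starts[k]:ends[k], drop = FALSE]
    vaF <- valFused[, starts[k]:ends[k], drop = FALSE]
    probe <- trainLinearProbe(rbind(trF, vaF),
                              c(trainData$labels, valData$labels), classes,
                              trainIdx = seq_len(nTr),
                              seed = config$seed + seedOff)
    predV <- probe$predict(nTr + seq_len(nrow(vaF)))
    evaluatePredictions(valData$labels, predV, classes)
  }
  imageOnly <- baseline(1L, 9L)
  hapticOnly <- baseline(3L, 10L)

  posNeg <- function(rep_) {
    cmP <- cmCounts(rep_$confusion)
    cl <- cmClasses(rep_$confusion)
    posI <- which(cl == "positive")
    truthPos <- rowSums(cmP)[posI] > 0
    tpr <- safeRatio(cmP[posI, posI], sum(cmP[posI, ]), "positive recall")
    tnr <- safeRatio(sum(cmP[-posI, -posI]), sum(cmP[-posI, ]),
                     "negative recall")
    (tpr + tnr) / 2
  }
  res <- list(report = report, imageOnly = imageOnly,
              hapticOnly = hapticOnly,
              posNegBalanced = c(fusion = posNeg(report),
                                 imageOnly = posNeg(imageOnly),
                                 hapticOnly = posNeg(hapticOnly)),
              fusion = fusion, config = config)
  if (!is.null(config$outDir))
    writeRunArtifacts(res, config$outDir, "heterogeneous")
  res
}

## Persist JSON reports + loss curves of an experiment run.
writeRunArtifacts <- function(res, outDir, tag) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (tag == "stage") {
    jsonlite::write_json(
      list(seed = res$config$seed, preset = res$config$preset,
           comparison = res$comparison,
           fusionTest = reportAsList(res$fusion@metrics$test)),
      file.path(outDir, "stage_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(res$fusion@history,
                     file.path(outDir, "fusion_loss.csv"),
                     row.names = FALSE)
    for (m in names(res$extractors))
      utils::write.csv(res$extractors[[m]]@history,
                       file.path(outDir, sprintf("%s_loss.csv", m)),
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(seed = res$config$seed,
           validation = reportAsList(res$report),
           imageOnly = reportAsList(res$imageOnly),
           hapticOnly = reportAsList(res$hapticOnly),
           posNegBalanced = as.list(res$posNegBalanced)),
      file.path(outDir, "heterogeneous_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(outDir)
}
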