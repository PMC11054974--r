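#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Labels
## ---------------------------------------------------------------------------

#' Maturity stages and heterogeneous-ripening categories
#'
#' The three maturity stages are defined by the red fraction on the exocarp
#' (and cross-section): immature < 10\% red, semi-mature 10--90\%, mature
#' > 90\%. The heterogeneity categories describe fruit whose exterior is
#' fully red (red fraction >= 95\%) but whose interior differs: negative
#' sample 1 (light-green cavity and flesh), negative sample 2 (white cavity),
#' and the positive sample (uniformly ripe inside and out).
#'
#' @return Character vectors of valid label values.
#' @examples
#' maturityStages()
#' heterogeneityCategories()
#' @export
maturityStages <- function() c("immature", "semi_mature", "mature")

#' @rdname maturityStages
#' @export
heterogeneityCategories <- function() c("negative1", "negative2", "positive")

allLabels <- function() c(maturityStages(), heterogeneityCategories())

isHeterogeneous <- function(label) label %in% heterogeneityCategories()

checkLabel <- function(label) {
  if (length(label) != 1L || !label %in% allLabels())
    stop("unknown maturity label: ", paste(label, collapse = ","),
         " (expected one of ", paste(allLabels(), collapse = ", "), ")")
  label
}

## ---------------------------------------------------------------------------
## Spectrum
## ---------------------------------------------------------------------------

#' Vis/NIR transmission spectrum with white/dark references
#'
#' Holds one acquisition over a strictly increasing wavelength grid
#' (default 350--1100 nm at 1 nm, 751 points): the raw transmission counts
#' `rRaw`, the white reference `rWhite` (light source on), the dark
#' reference `rDark` (source off), and, once [correctSpectrum()] has been
#' applied, the corrected signal R = (Rraw - Rd) / (Rw - Rd) together with a
#' per-channel validity mask (FALSE where Rw = Rd, i.e. the correction is
#' undefined).
#'
#' @slot wavelengths numeric, strictly increasing grid in nm.
#' @slot rRaw numeric raw counts, same length as the grid.
#' @slot rWhite,rDark numeric reference spectra, same length.
#' @slot rCorrected numeric corrected signal (length 0 until corrected).
#' @slot valid logical per-channel validity of the correction (length 0
#'   until corrected).
#' @export
setClass("Spectrum",
  representation(wavelengths = "numeric", rRaw = "numeric",
                 rWhite = "numeric", rDark = "numeric",
                 rCorrected = "numeric", valid = "logical"),
  prototype(rCorrected = numeric(0), valid = logical(0)))

setValidity("Spectrum", function(object) {
  n <- length(object@wavelengths)
  if (n < 2L)
    return("wavelength grid must have at least 2 points")
  if (any(diff(object@wavelengths) <= 0))
    return("wavelength grid must be strictly increasing")
  for (s in c("rRaw", "rWhite", "rDark"))
    if (length(slot(object, s)) != n)
      return(sprintf("%s must match the wavelength grid length (%d)", s, n))
  if (length(object@rCorrected) && length(object@rCorrected) != n)
    return("rCorrected must match the wavelength grid length")
  if (length(object@valid) && length(object@valid) != n)
    return("valid must match the wavelength grid length")
  if (length(object@rCorrected) &&
      any(!is.finite(object@rCorrected[object@valid])))
    return("corrected signal must be finite on valid channels")
  TRUE
})

#' Construct a Spectrum
#'
#' @param wavelengths strictly increasing grid in nm.
#' @param rRaw raw transmission counts.
#' @param rWhite,rDark white and dark reference spectra.
#' @return A [Spectrum-class] object (uncorrected).
#' @examples
#' wl <- seq(350, 1100, by = 1)
#' sp <- Spectrum(wl, rRaw = runif(length(wl)), rWhite = rep(2, length(wl)),
#'                rDark = rep(0, length(wl)))
#' @export
Spectrum <- function(wavelengths, rRaw, rWhite, rDark) {
  new("Spectrum", wavelengths = as.numeric(wavelengths),
      rRaw = as.numeric(rRaw), rWhite = as.numeric(rWhite),
      rDark = as.numeric(rDark))
}

#' Accessors for RipeFuse classes
#'
#' Slot accessors; user code should use these rather than `@`.
#'
#' @param x the object.
#' @param which for `splitFruits`, one of `"train"`, `"validation"`,
#'   `"test"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelengths)
#' @rdname accessors
#' @export
setMethod("rawSignal", "Spectrum", function(x) x@rRaw)
#' @rdname accessors
#' @export
setMethod("whiteReference", "Spectrum", function(x) x@rWhite)
#' @rdname accessors
#' @export
setMethod("darkReference", "Spectrum", function(x) x@rDark)
#' @rdname accessors
#' @export
setMethod("correctedSignal", "Spectrum", function(x) {
  if (!length(x@rCorrected))
    stop("spectrum has not been corrected yet; call correctSpectrum()")
  x@rCorrected
})

setMethod("show", "Spectrum", function(object) {
  rng <- range(object@wavelengths)
  cat(sprintf("Spectrum: %d channels, %.0f-%.0f nm, %s\n",
              length(object@wavelengths), rng[1], rng[2],
              if (length(object@rCorrected)) "corrected" else "uncorrected"))
})

## ---------------------------------------------------------------------------
## HapticTrace
## ---------------------------------------------------------------------------

#' Grip-pressure time series
#'
#' A uniformly sampled pressure trace in kPa recorded while a robotic
#' gripper clamps the fruit; the acquisition protocol samples at 100 Hz for
#' 15 s (1500 samples): an approach segment near zero, a grip ramp, and a
#' plateau whose level is the firmness proxy.
#'
#' @slot sampleRate sampling frequency in Hz.
#' @slot pressure numeric pressure series in kPa.
#' @export
setClass("HapticTrace",
  representation(sampleRate = "numeric", pressure = "numeric"))

setValidity("HapticTrace", function(object) {
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    return("sampleRate must be a single positive number")
  if (!length(object@pressure))
    return("pressure series must be non-empty")
  if (any(!is.finite(object@pressure)))
    return("pressure series must be finite")
  TRUE
})

#' Construct a HapticTrace
#'
#' @param pressure pressure series in kPa.
#' @param sampleRate sampling frequency in Hz (default 100).
#' @return A [HapticTrace-class].
#' @examples
#' tr <- HapticTrace(rep(20, 1500), sampleRate = 100)
#' traceDuration(tr)  # 15 s
#' @export
HapticTrace <- function(pressure, sampleRate = 100) {
  new("HapticTrace", sampleRate = as.numeric(sampleRate),
      pressure = as.numeric(pressure))
}

#' @rdname accessors
#' @export
setMethod("pressure", "HapticTrace", function(x) x@pressure)
#' @rdname accessors
#' @export
setMethod("sampleRate", "HapticTrace", function(x) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("traceDuration", "HapticTrace",
          function(x) length(x@pressure) / x@sampleRate)

setMethod("show", "HapticTrace", function(object) {
  cat(sprintf("HapticTrace: %d samples @ %g Hz (%.2f s), %.1f-%.1f kPa\n",
              length(object@pressure), object@sampleRate,
              traceDuration(object), min(object@pressure),
              max(object@pressure)))
})

## ---------------------------------------------------------------------------
## SegmentedImage
## ---------------------------------------------------------------------------

#' Threshold-segmented, standardised fruit image
#'
#' Result of [segmentImage()]: background pixels (grayscale <= threshold)
#' zeroed, cropped to the square bounding box of the foreground, and resized
#' to a fixed output size (150 x 150 by default).
#'
#' @slot pixels H x W x 3 numeric array, 8-bit scale (0--255), background 0.
#' @slot mask H x W logical foreground mask.
#' @slot empty TRUE when no foreground pixel exceeded the threshold.
#' @export
setClass("SegmentedImage",
  representation(pixels = "array", mask = "matrix", empty = "logical"),
  prototype(empty = FALSE))

setValidity("SegmentedImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (!identical(dim(object@mask), d[1:2]))
    return("mask must match the pixel array spatially")
  if (!is.logical(object@mask))
    return("mask must be logical")
  if (any(object@pixels[!array(object@mask, d)] != 0))
    return("background pixels must be zero outside the mask")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("imagePixels", "SegmentedImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("foregroundMask", "SegmentedImage", function(x) x@mask)

setMethod("show", "SegmentedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SegmentedImage: %dx%d, foreground %.1f%%%s\n", d[1], d[2],
              100 * mean(object@mask),
              if (object@empty) " (EMPTY foreground)" else ""))
})

## ---------------------------------------------------------------------------
## PhantomManifest
## ---------------------------------------------------------------------------

#' Acquisition manifest of a synthetic tomato dataset
#'
#' Indexes every acquisition record of a generated dataset: each fruit is
#' measured `nRotations` times (default 4, rotating 90 degrees around the
#' equator) by each of the three devices, so a fruit contributes
#' `nRotations x 3` records. The default full-size design (79 immature, 60
#' semi-mature, 75 mature fruits, 4 rotations) yields 214 fruits and 2568
#' acquisition records.
#'
#' @slot records data.frame with columns `fruit_id`, `rotation_index`
#'   (0-based), `modality` (image/spectrum/haptic), `label`, `file_path`.
#' @slot seed integer generator seed the dataset content derives from.
#' @slot classCounts named integer vector of fruits per label.
#' @slot nRotations rotations per fruit.
#' @export
setClass("PhantomManifest",
  representation(records = "data.frame", seed = "numeric",
                 classCounts = "integer", nRotations = "integer"))

setValidity("PhantomManifest", function(object) {
  need <- c("fruit_id", "rotation_index", "modality", "label", "file_path")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  nf <- length(unique(object@records$fruit_id))
  if (nrow(object@records) != nf * object@nRotations * 3L)
    return("record count must equal fruits x rotations x 3")
  per <- table(object@records$fruit_id)
  if (nf && any(per != object@nRotations * 3L))
    return("every fruit must have exactly nRotations x 3 records")
  if (sum(object@classCounts) != nf)
    return("classCounts must sum to the number of fruits")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("records", "PhantomManifest", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("nFruits", "PhantomManifest",
          function(x) length(unique(x@records$fruit_id)))
#' @rdname accessors
#' @export
setMethod("nAcquisitions", "PhantomManifest", function(x) nrow(x@records))

setMethod("show", "PhantomManifest", function(object) {
  cc <- object@classCounts[object@classCounts > 0]
  cat(sprintf("PhantomManifest: %d fruits x %d rotations -> %d records\n",
              nFruits(object), object@nRotations, nAcquisitions(object)))
  cat("  fruits per label: ",
      paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n", sep = "")
  cat("  seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## TomatoSample
## ---------------------------------------------------------------------------

#' One synthetic acquisition triplet
#'
#' All three modalities of one fruit at one rotation, plus the label and the
#' destructively measured quality attributes (soluble solids content in
#' degrees Brix and firmness in MPa).
#'
#' @slot fruitId character fruit identifier.
#' @slot rotation 0-based rotation index.
#' @slot label maturity stage or heterogeneity category.
#' @slot image H x W x 3 8-bit RGB array.
#' @slot spectrum a [Spectrum-class].
#' @slot haptic a [HapticTrace-class].
#' @slot ssc soluble solids content, Brix.
#' @slot firmness firmness, MPa.
#' @export
setClass("TomatoSample",
  representation(fruitId = "character", rotation = "integer",
                 label = "character", image = "array",
                 spectrum = "Spectrum", haptic = "HapticTrace",
                 ssc = "numeric", firmness = "numeric"))

setValidity("TomatoSample", function(object) {
  if (!object@label %in% allLabels())
    return("unknown label")
  if (length(object@ssc) && object@ssc <= 0)
    return("ssc must be positive")
  if (length(object@firmness) && object@firmness <= 0)
    return("firmness must be positive")
  TRUE
})

setMethod("show", "TomatoSample", function(object) {
  cat(sprintf("TomatoSample %s (rotation %d): %s, SSC %.2f Brix, firmness %.2f MPa\n",
              object@fruitId, object@rotation, object@label,
              object@ssc, object@firmness))
})

## ---------------------------------------------------------------------------
## Feature vectors
## ---------------------------------------------------------------------------

modalityDims <- c(image = 8192L, spectral = 10L, haptic = 64L)

#' Fixed-length modality embedding
#'
#' At the default (paper-faithful) extractor widths the dimensionalities are
#' image 8192, spectral 10, haptic 64. Reduced-width configurations produce
#' shorter image embeddings and are flagged on the extractor.
#'
#' @slot modality one of `image`, `spectral`, `haptic`.
#' @slot values numeric embedding.
#' @slot fruitId,rotation provenance of the acquisition.
#' @export
setClass("FeatureVector",
  representation(modality = "character", values = "numeric",
                 fruitId = "character", rotation = "integer"),
  prototype(fruitId = NA_character_, rotation = NA_integer_))

setValidity("FeatureVector", function(object) {
  if (!object@modality %in% names(modalityDims))
    return("modality must be image, spectral or haptic")
  if (any(!is.finite(object@values)))
    return("feature values must be finite")
  TRUE
})

#' Construct a FeatureVector
#' @param modality `image`, `spectral` or `haptic`.
#' @param values numeric embedding.
#' @param fruitId,rotation optional provenance.
#' @export
FeatureVector <- function(modality, values, fruitId = NA_character_,
                          rotation = NA_integer_) {
  new("FeatureVector", modality = modality, values = as.numeric(values),
      fruitId = fruitId, rotation = as.integer(rotation))
}

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureModality", "FeatureVector", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("featureDim", "FeatureVector", function(x) length(x@values))

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector [%s]: length %d\n", object@modality,
              length(object@values)))
})

#' Spliced cross-modal feature vector
#'
#' Concatenation `[m, n, z]` of the image, spectral and haptic embeddings in
#' that fixed order; length = |m| + |n| + |z| (8266 at default widths).
#'
#' @slot values numeric fused vector.
#' @slot segmentDims named integer vector (image/spectral/haptic lengths).
#' @slot fruitId,rotation provenance.
#' @export
setClass("FusedFeature",
  representation(values = "numeric", segmentDims = "integer",
                 fruitId = "character", rotation = "integer"),
  prototype(fruitId = NA_character_, rotation = NA_integer_))

setValidity("FusedFeature", function(object) {
  if (!identical(names(object@segmentDims), c("image", "spectral", "haptic")))
    return("segmentDims must be named image, spectral, haptic in order")
  if (length(object@values) != sum(object@segmentDims))
    return("fused length must equal the sum of the segment lengths")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("featureValues", "FusedFeature", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureDim", "FusedFeature", function(x) length(x@values))

setMethod("show", "FusedFeature", function(object) {
  cat(sprintf("FusedFeature: length %d = %s\n", length(object@values),
              paste(sprintf("%s %d", names(object@segmentDims),
                            object@segmentDims), collapse = " + ")))
})

## ---------------------------------------------------------------------------
## DatasetSplit
## ---------------------------------------------------------------------------

#' Fruit-level train/validation/test split
#'
#' Fruits (not acquisitions) are assigned to splits so that all rotations of
#' a fruit land in the same split and no rotation leakage can occur;
#' assignment is stratified by label with default fractions 64/16/20.
#'
#' @slot trainIds,valIds,testIds character fruit-id vectors.
#' @slot fractions numeric length-3 split fractions.
#' @slot seed split seed.
#' @export
setClass("DatasetSplit",
  representation(trainIds = "character", valIds = "character",
                 testIds = "character", fractions = "numeric",
                 seed = "numeric"))

setValidity("DatasetSplit", function(object) {
  ids <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(ids))
    return("split fruit sets must be disjoint")
  if (length(object@fractions) != 3L)
    return("fractions must have length 3")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("splitFruits", "DatasetSplit", function(x, which = c("train",
    "validation", "test")) {
  switch(match.arg(which), train = x@trainIds, validation = x@valIds,
         test = x@testIds)
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d validation / %d test fruits (fractions %s)\n",
              length(object@trainIds), length(object@valIds),
              length(object@testIds),
              paste(object@fractions, collapse = "/")))
})

## ---------------------------------------------------------------------------
## Evaluation containers
## ---------------------------------------------------------------------------

#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted classes, in a fixed class order.
#'
#' @slot counts K x K non-negative integer matrix.
#' @slot classes ordered class labels.
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix", classes = "character"))

setValidity("ConfusionMatrix", function(object) {
  k <- length(object@classes)
  if (!identical(dim(object@counts), c(k, k)))
    return("counts must be K x K for K classes")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("counts must be non-negative integers")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("cmCounts", "ConfusionMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("cmClasses", "ConfusionMatrix", function(x) x@classes)

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth, columns = predicted):\n")
  m <- object@counts
  dimnames(m) <- list(truth = object@classes, predicted = object@classes)
  print(m)
})

#' One-vs-rest binary tally
#'
#' @slot tp,tn,fp,fn non-negative counts.
#' @export
setClass("BinaryTally",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer"))

setValidity("BinaryTally", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (length(v) != 4L || any(v < 0))
    return("tp, tn, fp, fn must be single non-negative counts")
  TRUE
})

#' Construct a BinaryTally
#' @param tp,tn,fp,fn non-negative counts.
#' @export
BinaryTally <- function(tp, tn, fp, fn) {
  new("BinaryTally", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

setMethod("show", "BinaryTally", function(object) {
  cat(sprintf("BinaryTally: TP=%d TN=%d FP=%d FN=%d (total %d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

## ---------------------------------------------------------------------------
## Model wrappers
## ---------------------------------------------------------------------------

#' Unimodal feature extractor
#'
#' Wraps one modality network (VGG16-style CNN for images, 1-D CNN for
#' spectra, LSTM for haptic traces) together with its configuration,
#' training history, and the index of the feature-tap layer.
#'
#' @slot modality `image`, `spectral` or `haptic`.
#' @slot net internal network structure (list of layers).
#' @slot config the extractor configuration list.
#' @slot trained TRUE after [trainUnimodal()].
#' @slot history per-epoch loss log.
#' @slot metrics per-split metrics from the last training run.
#' @export
setClass("ModalityExtractor",
  representation(modality = "character", net = "list", config = "list",
                 trained = "logical", history = "data.frame",
                 metrics = "list"),
  prototype(trained = FALSE, history = data.frame(), metrics = list()))

#' @rdname accessors
#' @export
setMethod("featureModality", "ModalityExtractor", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("featureDim", "ModalityExtractor", function(x) x@config$featureDim)

setMethod("show", "ModalityExtractor", function(object) {
  cat(sprintf("ModalityExtractor [%s]: feature dim %d, %s%s\n",
              object@modality, object@config$featureDim,
              if (object@trained) "trained" else "untrained",
              if (isTRUE(object@config$paperConfig)) ""
              else " (non-paper configuration)"))
})

#' Fused fully connected residual classifier
#'
#' The classification head that consumes spliced cross-modal features:
#' four fully connected layers (input -> 512 -> 512 -> 256 -> classes), each
#' of the first three followed by batch normalisation, ReLU and dropout,
#' with a residual block (two 512-wide fully connected layers, each followed
#' by batch normalisation and dropout, identity skip added before the
#' activation) between the second and third layers.
#'
#' @slot net internal network structure.
#' @slot config fusion network configuration.
#' @slot classes class labels in output order.
#' @slot trained TRUE after [trainFusion()].
#' @slot history per-epoch train/validation loss log.
#' @slot metrics per-split metrics from the last training run.
#' @export
setClass("FusionClassifier",
  representation(net = "list", config = "list", classes = "character",
                 trained = "logical", history = "data.frame",
                 metrics = "list"),
  prototype(trained = FALSE, history = data.frame(), metrics = list()))

setMethod("show", "FusionClassifier", function(object) {
  cat(sprintf("FusionClassifier: input %d -> %s -> %d classes, %s (%s parameters)\n",
              object@config$inputDim,
              paste(object@config$widths, collapse = "-"),
              length(object@classes),
              if (object@trained) "trained" else "untrained",
              format(object@config$nParams, big.mark = ",")))
})
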