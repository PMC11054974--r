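#' Extract a modality feature embedding
#'
#' Runs a trained (or freshly initialised) modality extractor in evaluation
#' mode and returns the designated feature-tap activation: the flattened
#' final pooled convolutional output for images (8192-dim at default width),
#' the globally max-pooled third convolution block for spectra (10-dim), and
#' the final LSTM hidden state for haptic traces (64-dim).
#'
#' @param object a [ModalityExtractor-class] model.
#' @param x a single preprocessed input (array / numeric vector) or a batch
#'   (4-d array, matrix of rows, or list of inputs).
#' @param ... further arguments passed to methods.
#' @return A [FeatureVector-class] for a single input, or a numeric matrix
#'   with one row per input for a batch.
#' @export
setGeneric("extractFeatures", function(object, x, ...)
  standardGeneric("extractFeatures"))

#' Splice modality feature vectors into one fused vector
#'
#' Concatenates the image, spectral and haptic embeddings, in that fixed
#' order, into a single fused vector. No scaling or reweighting is applied;
#' at the default (paper-faithful) widths the result has length
#' 8192 + 10 + 64 = 8266.
#'
#' @param m image features ([FeatureVector-class] or matrix).
#' @param n spectral features.
#' @param z haptic features.
#' @param ... further arguments passed to methods.
#' @return A [FusedFeature-class] (vector inputs) or a fused matrix with one
#'   row per acquisition (matrix inputs).
#' @export
setGeneric("fuseFeatures", function(m, n, z, ...)
  standardGeneric("fuseFeatures"))

#' Predict the maturity class of fused features
#'
#' @param object a trained [FusionClassifier-class].
#' @param features a [FusedFeature-class], a numeric vector, or a matrix with
#'   one fused vector per row.
#' @param ... further arguments passed to methods.
#' @return A list with elements `label` (character) and `probabilities`
#'   (softmax class probabilities, rows summing to one). Ties are broken in
#'   favour of the lowest class index.
#' @export
setGeneric("predictMaturity", function(object, features, ...)
  standardGeneric("predictMaturity"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("rawSignal", function(x) standardGeneric("rawSignal"))
#' @rdname accessors
#' @export
setGeneric("whiteReference", function(x) standardGeneric("whiteReference"))
#' @rdname accessors
#' @export
setGeneric("darkReference", function(x) standardGeneric("darkReference"))
#' @rdname accessors
#' @export
setGeneric("correctedSignal", function(x) standardGeneric("correctedSignal"))
#' @rdname accessors
#' @export
setGeneric("pressure", function(x) standardGeneric("pressure"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("traceDuration", function(x) standardGeneric("traceDuration"))
#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setGeneric("foregroundMask", function(x) standardGeneric("foregroundMask"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("nFruits", function(x) standardGeneric("nFruits"))
#' @rdname accessors
#' @export
setGeneric("nAcquisitions", function(x) standardGeneric("nAcquisitions"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureModality", function(x) standardGeneric("featureModality"))
#' @rdname accessors
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))
#' @rdname accessors
#' @export
setGeneric("splitFruits", function(x, which = c("train", "validation", "test"))
  standardGeneric("splitFruits"))
#' @rdname accessors
#' @export
setGeneric("cmCounts", function(x) standardGeneric("cmCounts"))
#' @rdname accessors
#' @export
setGeneric("cmClasses", function(x) standardGeneric("cmClasses"))

#' Classification metrics
#'
#' `accuracy`, `precision` and `recall` evaluate the standard binary
#' formulas Accuracy = (TP+TN)/(TP+TN+FP+FN), Precision = TP/(TP+FP) and
#' Recall = TP/(TP+FN) on a [BinaryTally-class]. Applied to a
#' [ConfusionMatrix-class], `accuracy` returns the overall multiclass
#' accuracy (trace / total) and `precision`/`recall` return the one-vs-rest
#' value for `positive` (or the unweighted macro average over classes when
#' `positive` is missing). A zero denominator returns 0 with a warning.
#'
#' @param x a [BinaryTally-class] or [ConfusionMatrix-class].
#' @param ... for the confusion-matrix methods, optionally
#'   `positive = <class>`.
#' @return A fraction in \[0, 1\].
#' @name metrics
#' @export
setGeneric("accuracy", function(x, ...) standardGeneric("accuracy"))
#' @rdname metrics
#' @export
setGeneric("precision", function(x, ...) standardGeneric("precision"))
#' @rdname metrics
#' @export
setGeneric("recall", function(x, ...) standardGeneric("recall"))
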