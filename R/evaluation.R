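#' @include fusion.R
NULL

#' Build a multiclass confusion matrix
#'
#' Counts `cm[i, j]` = number of samples whose true class is `classes[i]`
#' and predicted class is `classes[j]`.
#'
#' @param truth,predictions equal-length label vectors.
#' @param classes ordered class labels; defaults to the classes appearing
#'   in `truth`/`predictions` in canonical label order.
#' @return A [ConfusionMatrix-class].
#' @examples
#' cm <- confusionMatrix(c("a", "a", "b"), c("a", "b", "b"),
#'                       classes = c("a", "b"))
#' cmCounts(cm)
#' @export
confusionMatrix <- function(truth, predictions, classes = NULL) {
  if (length(truth) != length(predictions))
    stop("truth and predictions must have equal length")
  if (is.null(classes)) {
    seen <- unique(c(truth, predictions))
    classes <- c(intersect(allLabels(), seen), setdiff(seen, allLabels()))
  }
  bad <- setdiff(unique(c(truth, predictions)), classes)
  if (length(bad))
    stop("labels outside the class set: ", paste(bad, collapse = ", "))
  k <- length(classes)
  counts <- matrix(0L, k, k)
  ti <- match(truth, classes)
  pi_ <- match(predictions, classes)
  for (i in seq_along(ti))
    counts[ti[i], pi_[i]] <- counts[ti[i], pi_[i]] + 1L
  new("ConfusionMatrix", counts = counts, classes = classes)
}

#' One-vs-rest reduction of a confusion matrix
#'
#' For a chosen positive class: TP is the diagonal cell, FP the rest of its
#' column, FN the rest of its row, TN everything else.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param positive the positive class label.
#' @return A [BinaryTally-class].
#' @export
binaryTally <- function(cm, positive) {
  if (!is(cm, "ConfusionMatrix"))
    stop("binaryTally expects a ConfusionMatrix")
  p <- match(positive, cm@classes)
  if (is.na(p))
    stop("positive class ", positive, " is not among: ",
         paste(cm@classes, collapse = ", "))
  m <- cm@counts
  tp <- m[p, p]
  fp <- sum(m[, p]) - tp
  fn <- sum(m[p, ]) - tp
  tn <- sum(m) - tp - fp - fn
  BinaryTally(tp, tn, fp, fn)
}

## Shared zero-denominator convention: 0 with a warning.
safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " has a zero denominator; returning 0 by convention")
    return(0)
  }
  num / den
}

#' @rdname metrics
setMethod("accuracy", "BinaryTally", function(x, ...) {
  safeRatio(x@tp + x@tn, x@tp + x@tn + x@fp + x@fn, "accuracy")
})

#' @rdname metrics
setMethod("precision", "BinaryTally", function(x, ...) {
  safeRatio(x@tp, x@tp + x@fp, "precision")
})

#' @rdname metrics
setMethod("recall", "BinaryTally", function(x, ...) {
  safeRatio(x@tp, x@tp + x@fn, "recall")
})

#' @rdname metrics
setMethod("accuracy", "ConfusionMatrix", function(x, ...) {
  safeRatio(sum(diag(x@counts)), sum(x@counts), "accuracy")
})

macroOverClasses <- function(cm, fun) {
  mean(vapply(cm@classes, function(cl) fun(binaryTally(cm, cl)),
              numeric(1)))
}

#' @rdname metrics
setMethod("precision", "ConfusionMatrix", function(x, positive = NULL,
                                                   ...) {
  if (is.null(positive)) macroOverClasses(x, precision)
  else precision(binaryTally(x, positive))
})

#' @rdname metrics
setMethod("recall", "ConfusionMatrix", function(x, positive = NULL, ...) {
  if (is.null(positive)) macroOverClasses(x, recall)
  else recall(binaryTally(x, positive))
})

#' Full metrics report for a set of predictions
#'
#' Computes the confusion matrix, overall accuracy, per-class one-vs-rest
#' precision and recall, and their unweighted macro averages. The binary
#' formulas are reported both per class and macro-averaged so either
#' single-number reading of a three-class task can be compared.
#'
#' @param truth,predictions equal-length label vectors.
#' @param classes ordered class labels.
#' @return A list of class `MetricsReport`: `confusion`
#'   ([ConfusionMatrix-class]), `accuracy`, `perClass` (data.frame with
#'   precision/recall per class), `macroPrecision`, `macroRecall`, `n`.
#' @examples
#' r <- evaluatePredictions(rep(maturityStages(), each = 5),
#'                          rep(maturityStages(), each = 5))
#' r$accuracy  # 1
#' @export
evaluatePredictions <- function(truth, predictions, classes = NULL) {
  cm <- confusionMatrix(truth, predictions, classes)
  per <- data.frame(
    class = cm@classes,
    precision = vapply(cm@classes,
                       function(cl) precision(binaryTally(cm, cl)),
                       numeric(1)),
    recall = vapply(cm@classes,
                    function(cl) recall(binaryTally(cm, cl)),
                    numeric(1)),
    row.names = NULL)
  structure(list(confusion = cm,
                 accuracy = accuracy(cm),
                 perClass = per,
                 macroPrecision = mean(per$precision),
                 macroRecall = mean(per$recall),
                 n = sum(cm@counts)),
            class = c("MetricsReport", "list"))
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport on %d samples: accuracy %.3f, macro precision %.3f, macro recall %.3f\n",
              x$n, x$accuracy, x$macroPrecision, x$macroRecall))
  invisible(x)
}

#' Evaluate a trained model on every split
#'
#' Recomputes predictions for the train/validation/test acquisitions and
#' returns one [evaluatePredictions()] report per split, plus a text table
#' in the layout Accuracy/Precision/Recall x Train/Validation/Test.
#'
#' @param model a trained [ModalityExtractor-class] (give `inputs`) or
#'   [FusionClassifier-class] (give `fused`).
#' @param inputs,fused the acquisition inputs matching the model type.
#' @param labels character labels per acquisition.
#' @param fruitIds fruit id per acquisition.
#' @param split a [DatasetSplit-class].
#' @param batchSize evaluation chunk size.
#' @return List of class `SplitMetrics` with `train`/`validation`/`test`
#'   reports and a `table` data.frame.
#' @export
evaluateModel <- function(model, labels, fruitIds, split, inputs = NULL,
                          fused = NULL, batchSize = 32L) {
  idx <- splitIndices(split, fruitIds, length(labels))
  if (all(!lengths(idx)))
    stop("empty split: no acquisitions to evaluate")
  if (is(model, "ModalityExtractor")) {
    if (is.null(inputs)) stop("inputs are required for a ModalityExtractor")
    classes <- intersect(allLabels(), unique(labels))
    makeBatch <- function(ii) stackBatch(model, inputs[ii])
  } else if (is(model, "FusionClassifier")) {
    if (is.null(fused)) stop("fused features are required for a FusionClassifier")
    classes <- model@classes
    makeBatch <- function(ii) fused[ii, , drop = FALSE]
  } else stop("unsupported model type")
  reports <- lapply(idx, function(ii) {
    if (!length(ii)) return(NULL)
    lo <- netLogits(model@net, makeBatch, ii, batchSize)
    pred <- classes[max.col(lo, ties.method = "first")]
    evaluatePredictions(labels[ii], pred, classes)
  })
  tab <- data.frame(metric = c("Accuracy", "Precision", "Recall"))
  for (s in names(reports)) {
    r <- reports[[s]]
    tab[[s]] <- if (is.null(r)) NA_real_ else
      c(r$accuracy, r$macroPrecision, r$macroRecall)
  }
  structure(c(reports, list(table = tab)),
            class = c("SplitMetrics", "list"))
}

#' Serialise a metrics report to JSON-ready lists
#'
#' @param report a `MetricsReport` from [evaluatePredictions()].
#' @return A plain list (counts, classes, metrics) suitable for
#'   `jsonlite::write_json()`.
#' @export
reportAsList <- function(report) {
  list(classes = cmClasses(report$confusion),
       confusion = unname(apply(cmCounts(report$confusion), 1, as.list)),
       accuracy = report$accuracy,
       perClass = report$perClass,
       macroPrecision = report$macroPrecision,
       macroRecall = report$macroRecall,
       n = report$n)
}
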