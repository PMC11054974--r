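test_that("confusion matrices count truth rows against prediction columns", {
  truth <- rep(maturityStages(), each = 5)
  cm <- confusionMatrix(truth, truth)
  expect_equal(cmCounts(cm), diag(c(5L, 5L, 5L)), ignore_attr = TRUE)

  # one mature fruit called semi-mature
  pred <- truth
  pred[11] <- "semi_mature"
  cm2 <- confusionMatrix(truth, pred, maturityStages())
  expect_equal(cmCounts(cm2)[3, 2], 1L)
  expect_equal(unname(rowSums(cmCounts(cm2))), c(5, 5, 5))

  # order invariance of the counts
  o <- sample(length(truth))
  expect_equal(cmCounts(confusionMatrix(truth[o], pred[o],
                                        maturityStages())),
               cmCounts(cm2))

  expect_error(confusionMatrix(truth, pred[-1]), "equal length")
  expect_error(confusionMatrix(c("a"), c("b"), classes = "a"), "outside")
})

test_that("one-vs-rest tallies reduce the matrix correctly", {
  truth <- rep(maturityStages(), each = 5)
  cm <- confusionMatrix(truth, truth)
  t1 <- binaryTally(cm, "mature")
  expect_equal(t1@fp, 0L)
  expect_equal(t1@fn, 0L)
  expect_equal(t1@tp + t1@tn + t1@fp + t1@fn, 15L)

  # hand-counted: one error in the positive row -> fn = 1
  pred <- truth
  pred[11] <- "semi_mature"
  t2 <- binaryTally(confusionMatrix(truth, pred, maturityStages()),
                    "mature")
  expect_equal(t2@tp, 4L)
  expect_equal(t2@fn, 1L)
  expect_equal(t2@fp, 0L)
  expect_equal(t2@tn, 10L)

  expect_error(binaryTally(cm, "ripe"), "not among")
})

test_that("metric formulas evaluate exactly with documented conventions", {
  expect_equal(accuracy(BinaryTally(1, 1, 0, 0)), 1)
  expect_equal(precision(BinaryTally(2, 0, 1, 0)), 2 / 3)
  expect_equal(recall(BinaryTally(3, 5, 2, 1)), 3 / 4)
  # degenerate denominators return 0 with a warning
  expect_warning(r <- recall(BinaryTally(0, 5, 2, 0)), "zero denominator")
  expect_equal(r, 0)
  expect_warning(p <- precision(BinaryTally(0, 5, 0, 2)),
                 "zero denominator")
  expect_equal(p, 0)
})

test_that("metrics agree with brute-force label counting on random inputs", {
  # Eqs for accuracy/precision/recall versus direct counting, many random
  # small three-class prediction sets
  set.seed(77)
  classes <- maturityStages()
  for (rep_ in 1:300) {
    n <- sample(3:30, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    cm <- confusionMatrix(truth, pred, classes)
    expect_equal(accuracy(cm), sum(truth == pred) / n)
    for (cl in classes) {
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      tn <- sum(truth != cl & pred != cl)
      tl <- binaryTally(cm, cl)
      expect_identical(c(tl@tp, tl@tn, tl@fp, tl@fn),
                       as.integer(c(tp, tn, fp, fn)))
      expect_equal(suppressWarnings(accuracy(tl)), (tp + tn) / n)
      expect_equal(suppressWarnings(precision(tl)),
                   if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(suppressWarnings(recall(tl)),
                   if (tp + fn == 0) 0 else tp / (tp + fn))
    }
  }
})

test_that("evaluateModel reports every split in the standard table layout", {
  set.seed(91)
  n <- 12
  feats <- rbind(matrix(rnorm(n * 8, 2), n),
                 matrix(rnorm(n * 8, -2), n),
                 matrix(rnorm(n * 8, 0), n))
  labels <- rep(maturityStages(), each = n)
  fruitIds <- sprintf("F%04d", seq_len(3 * n))
  split <- makeSplit(data.frame(fruit_id = fruitIds, label = labels),
                     seed = 1)
  cfg <- fusionNetConfig(inputDim = 8L, widths = c(8L, 8L, 6L),
                         dropout = 0, epochs = 15L, batchSize = 8L,
                         seed = 2L)
  # tiny 2-fruit validation split can miss a class entirely, triggering
  # the documented zero-denominator convention warning
  model <- suppressWarnings(
    trainFusion(buildFusionNetwork(cfg), feats, labels, fruitIds, split))
  rep_ <- suppressWarnings(
    evaluateModel(model, labels, fruitIds, split, fused = feats))
  expect_named(rep_, c("train", "validation", "test", "table"))
  expect_equal(rep_$table$metric, c("Accuracy", "Precision", "Recall"))
  for (s in c("train", "validation", "test")) {
    expect_s3_class(rep_[[s]], "MetricsReport")
    expect_equal(rep_$table[[s]],
                 c(rep_[[s]]$accuracy, rep_[[s]]$macroPrecision,
                   rep_[[s]]$macroRecall))
  }
  # the per-split metrics recorded at training time agree
  expect_equal(rep_$test$accuracy, model@metrics$test$accuracy)
  expect_error(evaluateModel(model, labels, fruitIds, split), "required")
})

test_that("reports aggregate per-class and macro metrics consistently", {
  set.seed(78)
  truth <- sample(maturityStages(), 60, replace = TRUE)
  pred <- truth
  pred[sample(60, 10)] <- sample(maturityStages(), 10, replace = TRUE)
  rep_ <- suppressWarnings(evaluatePredictions(truth, pred,
                                               maturityStages()))
  expect_s3_class(rep_, "MetricsReport")
  expect_equal(rep_$macroPrecision, mean(rep_$perClass$precision))
  expect_equal(rep_$macroRecall, mean(rep_$perClass$recall))
  expect_true(all(rep_$perClass$precision >= 0 &
                  rep_$perClass$precision <= 1))
  expect_gte(rep_$macroPrecision, min(rep_$perClass$precision))
  expect_lte(rep_$macroPrecision, max(rep_$perClass$precision))

  # metrics recomputed from the serialised confusion matrix match
  ser <- reportAsList(rep_)
  cmBack <- matrix(unlist(ser$confusion), nrow = 3, byrow = TRUE)
  expect_equal(cmBack, unname(cmCounts(rep_$confusion)))
  expect_equal(sum(diag(cmBack)) / sum(cmBack), rep_$accuracy)
  expect_equal(ser$n, 60)
})
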