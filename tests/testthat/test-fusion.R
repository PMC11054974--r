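test_that("feature splicing preserves length, order and provenance", {
  m <- FeatureVector("image", rnorm(8192), "F0001", 0L)
  n <- FeatureVector("spectral", rnorm(10), "F0001", 0L)
  z <- FeatureVector("haptic", rnorm(64), "F0001", 0L)
  fused <- fuseFeatures(m, n, z)
  expect_equal(featureDim(fused), 8266)        # 8192 + 10 + 64
  v <- featureValues(fused)
  expect_identical(v[1:8192], featureValues(m))
  expect_identical(v[8193:8202], featureValues(n))
  expect_identical(v[8203:8266], featureValues(z))

  zeros <- fuseFeatures(FeatureVector("image", rep(0, 8192)),
                        FeatureVector("spectral", rep(0, 10)),
                        FeatureVector("haptic", rep(0, 64)))
  expect_true(all(featureValues(zeros) == 0))

  # dimension mismatch names the offending modality
  expect_error(
    fuseFeatures(m, FeatureVector("spectral", rnorm(9)), z,
                 checkDims = c(image = 8192L, spectral = 10L,
                               haptic = 64L)),
    "spectral")
  # provenance mismatch
  z2 <- FeatureVector("haptic", rnorm(64), "F0002", 0L)
  expect_error(fuseFeatures(m, n, z2), "provenance")
  # wrong modality order
  expect_error(fuseFeatures(n, m, z), "order")

  # matrix form: per-row concatenation with recorded segment layout
  fm <- fuseFeatures(matrix(rnorm(20), 2), matrix(rnorm(6), 2),
                     matrix(rnorm(8), 2))
  expect_equal(dim(fm), c(2L, 17L))
  expect_equal(unname(attr(fm, "segmentDims")), c(10L, 3L, 4L))
  expect_error(fuseFeatures(matrix(rnorm(20), 2), matrix(rnorm(6), 3),
                            matrix(rnorm(8), 2)), "rows")
})

test_that("fusion network satisfies its shape and ablation contracts", {
  net <- buildFusionNetwork()
  x <- matrix(rnorm(8266), 1)
  out <- predictMaturity(net, x)
  expect_equal(dim(out$probabilities), c(1L, 3L))
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-9)

  xb <- matrix(rnorm(5 * 8266), 5)
  outb <- predictMaturity(net, xb)
  expect_equal(dim(outb$probabilities), c(5L, 3L))
  expect_equal(unname(rowSums(outb$probabilities)), rep(1, 5),
               tolerance = 1e-9)
  # argmax consistency and low-index tie-break
  expect_identical(outb$label,
                   maturityStages()[max.col(outb$probabilities,
                                            ties.method = "first")])

  expect_error(predictMaturity(net, rnorm(100)), "8266")
  expect_error(fusionNetConfig(residualWidth = 100L), "incompatible")
})

test_that("zeroing the residual branch reduces to the plain path", {
  cfg <- fusionNetConfig(inputDim = 12L, widths = c(8L, 8L, 6L),
                         dropout = 0, seed = 4L)
  model <- buildFusionNetwork(cfg)
  # zero every parameter of the residual branch
  layers <- model@net$layers
  resIdx <- which(vapply(layers, function(l) l$type == "residual",
                         logical(1)))
  for (i in seq_along(layers[[resIdx]]$sub)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      if (!is.null(layers[[resIdx]]$sub[[i]][[nm]]))
        layers[[resIdx]]$sub[[i]][[nm]][] <- 0
    }
  }
  model@net$layers <- layers

  x <- matrix(rnorm(3 * 12), 3)
  got <- RipeFuse:::netForward(model@net, x, training = FALSE)$out

  # independent oracle: plain 4-layer path computed by hand in eval mode
  # (batch norm with fresh running stats: xhat = x / sqrt(1 + eps))
  bnEval <- function(h, l) {
    xh <- (h - rep(l$runMean, each = nrow(h))) /
      rep(sqrt(l$runVar + l$eps), each = nrow(h))
    xh * rep(l$gamma, each = nrow(h)) + rep(l$beta, each = nrow(h))
  }
  lin <- function(h, l) h %*% l$W + rep(l$b, each = nrow(h))
  relu <- function(h) pmax(h, 0)
  L <- model@net$layers
  h <- relu(bnEval(lin(x, L[[1]]), L[[2]]))
  h <- relu(bnEval(lin(h, L[[5]]), L[[6]]))
  h <- relu(h)                                 # skip adds zero, then ReLU
  h <- relu(bnEval(lin(h, L[[11]]), L[[12]]))
  expected <- lin(h, L[[15]])
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("splits are stratified, leakage-free and deterministic", {
  m <- generateManifest(100, 0, 0, seed = 3)
  sp <- makeSplit(m, seed = 5)
  expect_length(splitFruits(sp, "train"), 64)
  expect_length(splitFruits(sp, "validation"), 16)
  expect_length(splitFruits(sp, "test"), 20)

  m2 <- generateManifest(10, 10, 10, seed = 3)
  sp2 <- makeSplit(m2, seed = 5)
  all2 <- c(splitFruits(sp2, "train"), splitFruits(sp2, "validation"),
            splitFruits(sp2, "test"))
  expect_setequal(all2, unique(records(m2)$fruit_id))
  expect_equal(anyDuplicated(all2), 0L)
  # stratification: each class contributes 6/2/2
  fruits <- unique(records(m2)[, c("fruit_id", "label")])
  for (lab in maturityStages()) {
    ids <- fruits$fruit_id[fruits$label == lab]
    expect_length(intersect(ids, splitFruits(sp2, "train")), 6)
    expect_length(intersect(ids, splitFruits(sp2, "test")), 2)
  }
  # all rotations of a fruit follow its split (fruit-level assignment)
  rec <- records(m2)
  trainRec <- rec[rec$fruit_id %in% splitFruits(sp2, "train"), ]
  expect_equal(nrow(trainRec), 18 * 4 * 3)

  expect_identical(makeSplit(m2, seed = 5), sp2)
  expect_error(makeSplit(m2, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(makeSplit(generateManifest(2, 5, 5, seed = 1)), "too few")
})

test_that("fusion training fits separable features and predicts labels", {
  # three well-separated clusters in 20 dimensions
  set.seed(6)
  n <- 20
  centers <- rbind(rep(c(3, 0, 0), c(7, 7, 6)),
                   rep(c(0, 3, 0), c(7, 7, 6)),
                   rep(c(0, 0, 3), c(7, 7, 6)))
  feats <- centers[rep(1:3, each = n), ] + matrix(rnorm(3 * n * 20, 0, 0.4),
                                                  3 * n)
  labels <- rep(maturityStages(), each = n)
  fruitIds <- sprintf("F%04d", seq_len(3 * n))
  split <- makeSplit(data.frame(fruit_id = fruitIds, label = labels),
                     seed = 2)
  cfg <- fusionNetConfig(inputDim = 20L, widths = c(16L, 16L, 8L),
                         dropout = 0.2, epochs = 30L, batchSize = 16L,
                         seed = 3L)
  model <- trainFusion(buildFusionNetwork(cfg), feats, labels, fruitIds,
                       split)
  expect_true(model@trained)
  expect_gt(model@metrics$test$accuracy, 0.8)
  expect_lt(model@history$trainLoss[nrow(model@history)],
            model@history$trainLoss[1])
  expect_equal(nrow(model@history), 30)

  pred <- predictMaturity(model, feats[1, ])
  expect_true(pred$label %in% maturityStages())

  expect_error(trainFusion(buildFusionNetwork(cfg), feats, labels[-1]),
               "agree")
  expect_error(trainFusion(buildFusionNetwork(cfg), feats,
                           rep("mature", 3 * n)), "single class")
  badCfg <- fusionNetConfig(inputDim = 21L, widths = c(16L, 16L, 8L))
  expect_error(trainFusion(buildFusionNetwork(badCfg), feats, labels),
               "input dimension")
})
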