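test_that("manifest layout matches the acquisition design", {
  m <- generateManifest(79, 60, 75, nRotations = 4, seed = 1)
  expect_equal(nFruits(m), 214)
  expect_equal(nAcquisitions(m), 2568)
  perFruit <- table(records(m)$fruit_id)
  expect_true(all(perFruit == 12))
  expect_equal(sort(unique(records(m)$modality)),
               c("haptic", "image", "spectrum"))

  tiny <- generateManifest(1, 0, 0, nRotations = 1, seed = 2)
  expect_equal(nFruits(tiny), 1)
  expect_equal(nAcquisitions(tiny), 3)

  expect_identical(generateManifest(5, 4, 3, seed = 7),
                   generateManifest(5, 4, 3, seed = 7))

  expect_error(generateManifest(-1, 0, 0), "non-negative")
  expect_error(generateManifest(1, 1, 1, nRotations = 0), "at least 1")

  het <- generateManifest(0, 0, 0, nRotations = 1,
                          heterogeneous = c(negative1 = 2, negative2 = 2,
                                            positive = 2))
  expect_equal(nFruits(het), 6)
  expect_setequal(unique(records(het)$label), heterogeneityCategories())
})

test_that("quality attributes recover the class means with a monotone trend", {
  q <- generateQualityAttributes("mature", n = 1000, seed = 11)
  cfg <- phantomDefaults()
  expect_equal(mean(q$ssc), 5.5, tolerance = 3 * cfg$ssc$sd / sqrt(1000) / 5.5)

  qi <- generateQualityAttributes("immature", n = 1000, seed = 12)
  expect_equal(mean(qi$firmness), 2.82,
               tolerance = 3 * cfg$firmness$sd / sqrt(1000) / 2.82)

  exact <- generateQualityAttributes("semi_mature", n = 50, seed = 13,
                                     sscSd = 0, firmnessSd = 0)
  expect_true(all(exact$ssc == 4.85))
  expect_true(all(exact$firmness == 1.96))

  expect_error(generateQualityAttributes("overripe"), "unknown")

  # mixed batch: SSC rises while firmness falls across stages
  mixed <- do.call(rbind, lapply(maturityStages(), function(lab)
    generateQualityAttributes(lab, n = 200, seed = 14)))
  expect_lt(stats::cor(mixed$ssc, mixed$firmness), 0)
  means <- vapply(maturityStages(), function(lab)
    mean(generateQualityAttributes(lab, n = 300, seed = 15)$ssc),
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("rendered images respect the red-fraction stage definitions", {
  bounds <- list(immature = c(0, 0.10), semi_mature = c(0.10, 0.90),
                 mature = c(0.90, 1), negative1 = c(0.95, 1),
                 negative2 = c(0.95, 1), positive = c(0.95, 1))
  for (lab in names(bounds)) {
    for (s in 1:4) {
      img <- renderTomatoImage(lab, rotation = s %% 4, seed = 100 + s)
      rf <- redFraction(img)
      expect_gte(rf, bounds[[lab]][1])
      expect_lte(rf, bounds[[lab]][2])
      if (lab == "immature") expect_lt(rf, 0.10)
      if (lab == "mature") expect_gt(rf, 0.90)
    }
  }
  # heterogeneity categories are indistinguishable from mature by design
  expect_gte(redFraction(renderTomatoImage("negative2", seed = 5)), 0.95)

  # dark background below the segmentation threshold
  img <- renderTomatoImage("mature", seed = 6)
  gray <- rgbToGray(img)
  expect_lt(max(gray[!foregroundMask(segmentImage(img, outSize = NA))]), 50)

  # byte-identical re-render under a fixed seed
  expect_identical(renderTomatoImage("semi_mature", 1, seed = 42),
                   renderTomatoImage("semi_mature", 1, seed = 42))
})

test_that("spectra follow the designed template and band ordering", {
  sp0 <- synthesizeSpectrum("mature", noiseSd = 0, seed = 1)
  cs0 <- correctedSignal(correctSpectrum(sp0))
  expect_equal(cs0, RipeFuse:::spectralTemplate("mature", phantomDefaults()),
               tolerance = 1e-12)

  wl <- wavelengths(sp0)
  avg <- meanCorrectedSpectrum("mature", 60)
  expect_equal(peakWavelength(avg, wl, c(580, 680)), 630)

  band <- wl >= 600 & wl <= 950
  bandMean <- function(lab) mean(meanCorrectedSpectrum(lab, 20,
                                                       seedBase = 300)[band])
  expect_gt(bandMean("mature"), bandMean("semi_mature"))
  expect_gt(bandMean("semi_mature"), bandMean("immature"))

  # negative 1 sits 5 noise units below the positive template, negative 2
  # only 1 unit: spectra separate negative 1 clearly, negative 2 barely
  cfg <- phantomDefaults()
  tPos <- RipeFuse:::spectralTemplate("positive", cfg)
  t1 <- RipeFuse:::spectralTemplate("negative1", cfg)
  t2 <- RipeFuse:::spectralTemplate("negative2", cfg)
  gap1 <- mean((tPos - t1)[band])
  gap2 <- mean((tPos - t2)[band])
  expect_gt(gap1, 4 * cfg$spectrum$noiseSd)
  expect_lt(gap2, 1.2 * cfg$spectrum$noiseSd)

  badCfg <- phantomDefaults()
  badCfg$spectrum$gridStep <- -1
  expect_error(synthesizeSpectrum("mature", badCfg), "strictly increasing")
})

test_that("haptic traces have the protocol length and disjoint plateaus", {
  tr <- synthesizeHapticTrace("mature", seed = 1)
  expect_equal(length(pressure(tr)), 1500)     # 100 Hz x 15 s
  expect_equal(sampleRate(tr), 100)
  expect_equal(traceDuration(tr), 15)

  ranges <- list(mature = c(13, 26), semi_mature = c(26, 46),
                 immature = c(52, 65))
  tol <- 0.3                                   # plateau-summary precision
  lv <- lapply(names(ranges), function(lab)
    vapply(1:40, function(i)
      plateauPressure(synthesizeHapticTrace(lab, seed = 7000 + i)),
      numeric(1)))
  names(lv) <- names(ranges)
  for (lab in names(ranges)) {
    expect_gte(min(lv[[lab]]), ranges[[lab]][1] - tol)
    expect_lte(max(lv[[lab]]), ranges[[lab]][2] + tol)
  }
  # class-conditional plateaus are disjoint by construction
  expect_lt(max(lv$mature), min(lv$semi_mature))
  expect_lt(max(lv$semi_mature), min(lv$immature))

  # heterogeneity categories: hard negatives near 29 kPa, soft positive
  # near 13 kPa
  het <- vapply(c("negative1", "negative2", "positive"), function(lab)
    mean(vapply(1:30, function(i)
      plateauPressure(synthesizeHapticTrace(lab, seed = 8000 + i)),
      numeric(1))), numeric(1))
  expect_equal(unname(het[["negative1"]]), 29, tolerance = 0.05)
  expect_equal(unname(het[["negative2"]]), 29, tolerance = 0.05)
  expect_equal(unname(het[["positive"]]), 13, tolerance = 0.05)

  # vibration noise lives above the 10 Hz cutoff
  raw <- pressure(synthesizeHapticTrace("mature", seed = 3))
  spec <- Mod(stats::fft(raw - mean(raw)))^2
  freqs <- (seq_along(raw) - 1) / length(raw) * 100
  half <- freqs <= 50
  expect_gt(sum(spec[half & freqs > 10]), 0)
})

test_that("datasets round-trip through disk", {
  dir <- withr::local_tempdir()
  m <- generateManifest(1, 0, 0, nRotations = 1, seed = 9)
  writeDataset(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, recursive = TRUE, pattern = "png$|csv$"), 3)

  ds <- readDataset(dir)
  expect_equal(nAcquisitions(ds$manifest), 3)
  s <- readSample(ds, "F0001", 0)
  orig <- generateDataset(m)[[1]]
  expect_identical(s@image, orig@image)        # 8-bit exact
  expect_equal(rawSignal(s@spectrum), rawSignal(orig@spectrum),
               tolerance = 1e-6)
  expect_equal(pressure(s@haptic), pressure(orig@haptic), tolerance = 1e-6)
  expect_equal(s@ssc, orig@ssc, tolerance = 1e-6)

  # refuses to clobber an existing dataset unless told to
  expect_error(writeDataset(m, dir), "overwrite")
  expect_silent(writeDataset(m, dir, overwrite = TRUE))
})

test_that("dataset generation is deterministic under a fixed seed", {
  m <- generateManifest(2, 1, 1, nRotations = 2, seed = 21)
  a <- generateDataset(m)
  b <- generateDataset(m)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]@image, b[[i]]@image)
    expect_identical(pressure(a[[i]]@haptic), pressure(b[[i]]@haptic))
    expect_identical(rawSignal(a[[i]]@spectrum), rawSignal(b[[i]]@spectrum))
  }
  # rotations share fruit-level statistics
  expect_identical(a[[1]]@ssc, a[[2]]@ssc)
  expect_identical(a[[1]]@fruitId, a[[2]]@fruitId)
})
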