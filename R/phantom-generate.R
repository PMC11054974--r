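#' @include phantom-config.R
NULL

#' Generate an acquisition manifest
#'
#' Lays out a synthetic dataset: one record per fruit, rotation and
#' modality. Each fruit is acquired `nRotations` times (rotating around the
#' equator) by each of the three devices, so a fruit contributes
#' `nRotations * 3` records; the default full-size design (79/60/75 fruits,
#' 4 rotations) yields 2568 records. The manifest itself is deterministic;
#' the stored `seed` drives all downstream content generation, so equal
#' seeds give byte-identical datasets.
#'
#' @param nImmature,nSemi,nMature fruits per maturity stage (>= 0).
#' @param nRotations acquisitions per fruit and device (>= 1, default 4).
#' @param seed integer generator seed recorded in the manifest.
#' @param heterogeneous optional named counts for the heterogeneous-ripening
#'   categories, e.g. `c(negative1 = 6, negative2 = 6, positive = 6)`.
#' @return A [PhantomManifest-class].
#' @examples
#' m <- generateManifest(79, 60, 75, nRotations = 4, seed = 1)
#' nFruits(m)        # 214
#' nAcquisitions(m)  # 2568
#' @export
generateManifest <- function(nImmature, nSemi, nMature, nRotations = 4L,
                             seed = 1L,
                             heterogeneous = c(negative1 = 0L,
                                               negative2 = 0L,
                                               positive = 0L)) {
  counts <- c(immature = nImmature, semi_mature = nSemi, mature = nMature)
  het <- c(negative1 = 0L, negative2 = 0L, positive = 0L)
  if (length(heterogeneous)) {
    if (is.null(names(heterogeneous)) && length(heterogeneous) == 3L)
      names(heterogeneous) <- heterogeneityCategories()
    bad <- setdiff(names(heterogeneous), heterogeneityCategories())
    if (length(bad))
      stop("unknown heterogeneity categories: ", paste(bad, collapse = ", "))
    het[names(heterogeneous)] <- heterogeneous
  }
  counts <- c(counts, het)
  if (any(counts < 0))
    stop("fruit counts must be non-negative, got: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  if (nRotations < 1)
    stop("nRotations must be at least 1")
  counts <- as.integer(counts)
  names(counts) <- c(maturityStages(), heterogeneityCategories())
  labels <- rep(names(counts), counts)
  n <- length(labels)
  fruitIds <- sprintf("F%04d", seq_len(n))
  rot <- seq_len(nRotations) - 1L
  modalities <- c("image", "spectrum", "haptic")
  subdir <- c(image = "images", spectrum = "spectra", haptic = "haptic")
  ext <- c(image = "png", spectrum = "csv", haptic = "csv")
  rec <- expand.grid(modality = modalities, rotation_index = rot,
                     fruit = seq_len(n), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  records <- data.frame(
    fruit_id = fruitIds[rec$fruit],
    rotation_index = as.integer(rec$rotation_index),
    modality = rec$modality,
    label = labels[rec$fruit],
    file_path = sprintf("%s/%s_r%d.%s", subdir[rec$modality],
                        fruitIds[rec$fruit], rec$rotation_index,
                        ext[rec$modality]),
    stringsAsFactors = FALSE)
  new("PhantomManifest", records = records, seed = as.numeric(seed),
      classCounts = counts, nRotations = as.integer(nRotations))
}

#' Draw class-conditional quality attributes
#'
#' Soluble solids content (Brix) and firmness (MPa) are drawn from
#' truncated Gaussians around the class means (SSC 4.15/4.85/5.5 Brix and
#' firmness 2.82/1.96/1.1 MPa for immature/semi-mature/mature); draws are
#' truncated to positive values. With `sscSd = firmnessSd = 0` every draw
#' equals the class mean exactly.
#'
#' @param label maturity stage or heterogeneity category.
#' @param n number of fruits to draw for.
#' @param config generator configuration, see [phantomDefaults()].
#' @param seed optional seed (restores the caller's RNG state).
#' @param sscSd,firmnessSd spread overrides (default from `config`).
#' @return data.frame with columns `ssc` and `firmness`, `n` rows.
#' @examples
#' q <- generateQualityAttributes("mature", n = 5, seed = 1)
#' @export
generateQualityAttributes <- function(label, n = 1L,
                                      config = phantomDefaults(),
                                      seed = NULL,
                                      sscSd = config$ssc$sd,
                                      firmnessSd = config$firmness$sd) {
  checkLabel(label)
  withSeed(seed, {
    ssc <- rtruncPos(n, config$ssc$mean[[label]], sscSd)
    firmness <- rtruncPos(n, config$firmness$mean[[label]], firmnessSd)
    data.frame(ssc = ssc, firmness = firmness)
  })
}

## Positive-truncated Gaussian by rejection; exact mean when sd = 0.
rtruncPos <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Render a synthetic tomato image
#'
#' Draws a tomato-like disc on a dark background (gray value below the
#' segmentation threshold of 50) whose red-surface fraction respects the
#' stage definition: immature < 10\%, semi-mature 10--90\%, mature > 90\%,
#' and every heterogeneity category >= 95\% (a fully red exterior, by design
#' indistinguishable from mature in the image modality). The red/unripe
#' boundary is a wiggly half-plane through the fruit whose orientation
#' follows the rotation index; rotation and the random stream perturb only
#' nuisance geometry (disc radius, ellipticity, boundary wiggle, pixel
#' colour jitter), never the class statistics.
#'
#' @param label maturity stage or heterogeneity category.
#' @param rotation 0-based rotation index (orients the blotch boundary).
#' @param config generator configuration.
#' @param seed optional seed.
#' @param redFrac optional red-fraction override in \[0, 1\] (drawn from the
#'   label's band when NULL); use it to hold a fruit's red fraction fixed
#'   across rotations.
#' @return H x W x 3 integer array on the 0--255 scale.
#' @examples
#' img <- renderTomatoImage("mature", seed = 7)
#' redFraction(img) > 0.9
#' @export
renderTomatoImage <- function(label, rotation = 0L,
                              config = phantomDefaults(), seed = NULL,
                              redFrac = NULL) {
  checkLabel(label)
  ic <- config$image
  withSeed(seed, {
    sz <- ic$size
    if (is.null(redFrac)) {
      band <- ic$redBand[[label]]
      redFrac <- stats::runif(1, band[1], band[2])
    }
    r <- stats::runif(1, ic$radiusFrac[1], ic$radiusFrac[2]) * sz
    ecc <- stats::runif(1, 0.94, 1.06)
    cx <- sz / 2 + stats::runif(1, -2, 2)
    cy <- sz / 2 + stats::runif(1, -2, 2)
    xs <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
    ys <- matrix(seq_len(sz), sz, sz)
    inside <- ((xs - cx) / (r * ecc))^2 + ((ys - cy) / r)^2 <= 1
    theta <- rotation * pi / 2 + stats::runif(1, -0.25, 0.25)
    phase <- stats::runif(1, 0, 2 * pi)
    un <- ((xs - cx) * cos(theta) + (ys - cy) * sin(theta)) / r
    vn <- (-(xs - cx) * sin(theta) + (ys - cy) * cos(theta)) / r
    proj <- un + ic$wiggleAmp * sin(2 * pi * 1.7 * vn + phase) * 4
    pf <- proj[inside]
    thr <- if (redFrac <= 0) -Inf else stats::quantile(pf, redFrac,
                                                      names = FALSE)
    red <- inside & (proj <= thr)
    img <- array(ic$background, c(sz, sz, 3))
    nIn <- sum(inside)
    nRed <- sum(red)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- ic$unripeRGB[ch] +
        stats::rnorm(nIn, 0, ic$colorJitter)
      plane[red] <- ic$ripeRGB[ch] + stats::rnorm(nRed, 0, ic$colorJitter)
      img[, , ch] <- plane
    }
    storage.mode(img) <- "double"
    img <- round(pmin(pmax(img, 0), 255))
    img
  })
}

## Smooth class-conditional corrected-spectrum template.
spectralTemplate <- function(label, config) {
  checkLabel(label)
  sc <- config$spectrum
  wl <- spectrumGrid(config)
  base <- 0.15 + 0.10 * stats::plogis((wl - 450) / 30)
  scale <- sc$classScale[[label]]
  tmpl <- base
  for (i in seq_along(sc$peaks))
    tmpl <- tmpl + scale * sc$peakAmp[i] *
      exp(-0.5 * ((wl - sc$peaks[i]) / sc$widths[i])^2)
  if (isHeterogeneous(label)) {
    off <- sc$heteroOffsetNoiseUnits[[label]] * sc$noiseSd
    window <- stats::plogis((wl - sc$offsetBand[1]) / 8) *
      stats::plogis((sc$offsetBand[2] - wl) / 8)
    tmpl <- tmpl - off * window
  }
  tmpl
}

#' Synthesise a raw spectrum with white/dark references
#'
#' Emits the full correction triplet: white reference Rw (instrument
#' response with the source on), dark reference Rd (source off), and a raw
#' signal Rraw constructed so that the black-and-white-corrected spectrum
#' R = (Rraw - Rd)/(Rw - Rd) equals a smooth class-conditional template
#' (Gaussian absorption features at 630/730/830/1070 nm over a gentle
#' baseline) plus white noise. Class amplitude scales order the corrected
#' band mean over 600--950 nm as mature > semi-mature > immature; negative
#' sample 1 is offset from the positive template by 5x the noise scale,
#' negative sample 2 by only 1x (so spectra separate negative 1 but barely
#' negative 2).
#'
#' @param label maturity stage or heterogeneity category.
#' @param config generator configuration; the wavelength grid defaults to
#'   350--1100 nm at 1 nm (751 points) and must be strictly increasing.
#' @param seed optional seed.
#' @param noiseSd corrected-domain noise standard deviation; 0 makes the
#'   corrected spectrum equal the class template exactly.
#' @return An uncorrected [Spectrum-class] (apply [correctSpectrum()]).
#' @examples
#' sp <- synthesizeSpectrum("mature", seed = 3)
#' @export
synthesizeSpectrum <- function(label, config = phantomDefaults(),
                               seed = NULL,
                               noiseSd = config$spectrum$noiseSd) {
  checkLabel(label)
  wl <- spectrumGrid(config)
  if (any(diff(wl) <= 0))
    stop("wavelength grid must be strictly increasing")
  sc <- config$spectrum
  tmpl <- spectralTemplate(label, config)
  env <- 0.5 + 0.5 * exp(-0.5 * ((wl - 725) / 260)^2)
  rW <- sc$whiteLevel * env
  rD <- sc$darkLevel + 0.01 * (wl - wl[1])
  withSeed(seed, {
    corrected <- tmpl + stats::rnorm(length(wl), 0, noiseSd)
    rRaw <- rD + corrected * (rW - rD)
    Spectrum(wl, rRaw, rW, rD)
  })
}

## Class-conditional plateau draw in kPa.
drawPlateau <- function(label, config) {
  if (isHeterogeneous(label)) {
    p <- config$plateau$hetero[[label]]
    max(stats::rnorm(1, p[["mean"]], p[["sd"]]), 1)
  } else {
    rng <- config$plateau$range[[label]]
    stats::runif(1, rng[1], rng[2])
  }
}

#' Synthesise a grip-pressure trace
#'
#' Produces a 100 Hz x 15 s (1500-sample) pressure series in kPa: an
#' approach segment near zero, a smooth grip ramp, and a plateau whose
#' level is drawn uniformly from 13--26 / 26--46 / 52--65 kPa for
#' mature/semi-mature/immature fruit, and around 29 kPa (negative samples
#' 1 and 2) or 13 kPa (positive sample) for the heterogeneity categories.
#' Additive gripper vibration lives in the 20--40 Hz band (well above the
#' 10 Hz filter cutoff) plus a little white sensor noise, so the
#' Butterworth preprocessing stage has something real to remove.
#'
#' @param label maturity stage or heterogeneity category.
#' @param config generator configuration.
#' @param seed optional seed.
#' @param plateau optional plateau level override in kPa (drawn from the
#'   label's distribution when NULL); use it to share a fruit's plateau
#'   across its equatorial rotations.
#' @return A [HapticTrace-class] of `round(sampleRate * duration)` samples.
#' @examples
#' tr <- synthesizeHapticTrace("immature", seed = 5)
#' length(pressure(tr))  # 1500
#' @export
synthesizeHapticTrace <- function(label, config = phantomDefaults(),
                                  seed = NULL, plateau = NULL) {
  checkLabel(label)
  hc <- config$haptic
  withSeed(seed, {
    n <- round(hc$sampleRate * hc$duration)
    tt <- (seq_len(n) - 1) / hc$sampleRate
    if (is.null(plateau))
      plateau <- drawPlateau(label, config)
    u <- pmin(pmax((tt - hc$approachEnd) / (hc$rampEnd - hc$approachEnd),
                   0), 1)
    profile <- plateau * u * u * (3 - 2 * u)
    amp <- stats::runif(1, hc$vibAmp[1], hc$vibAmp[2])
    f <- stats::runif(1, hc$vibBand[1], hc$vibBand[2])
    phi <- stats::runif(1, 0, 2 * pi)
    vib <- amp * sin(2 * pi * f * tt + phi)
    noise <- stats::rnorm(n, 0, hc$whiteSd)
    HapticTrace(pmax(profile + vib + noise, 0), hc$sampleRate)
  })
}

#' Generate one complete acquisition triplet
#'
#' Draws image, spectrum and haptic trace for one fruit at one rotation,
#' plus quality attributes. Fruit-level properties (red fraction, plateau
#' level, SSC, firmness) can be passed in so that all rotations of a fruit
#' share them, which is how [generateDataset()] uses this function.
#'
#' @param label maturity stage or heterogeneity category.
#' @param fruitId,rotation identifiers recorded on the sample.
#' @param config generator configuration.
#' @param seed optional seed.
#' @param quality optional 1-row data.frame from
#'   [generateQualityAttributes()].
#' @param plateau,redFrac optional fruit-level overrides.
#' @return A [TomatoSample-class].
#' @export
generateSample <- function(label, fruitId = "F0001", rotation = 0L,
                           config = phantomDefaults(), seed = NULL,
                           quality = NULL, plateau = NULL, redFrac = NULL) {
  checkLabel(label)
  withSeed(seed, {
    if (is.null(quality))
      quality <- generateQualityAttributes(label, 1L, config)
    img <- renderTomatoImage(label, rotation, config, redFrac = redFrac)
    sp <- synthesizeSpectrum(label, config)
    tr <- synthesizeHapticTrace(label, config, plateau = plateau)
    new("TomatoSample", fruitId = fruitId, rotation = as.integer(rotation),
        label = label, image = img, spectrum = sp, haptic = tr,
        ssc = quality$ssc[1], firmness = quality$firmness[1])
  })
}

#' Materialise all samples of a manifest in memory
#'
#' Generates every acquisition triplet of a manifest deterministically from
#' the manifest seed: fruit-level attributes (quality, plateau level, red
#' fraction) are drawn once per fruit, rotations add only nuisance
#' variation. For large designs prefer [writeDataset()], which streams to
#' disk.
#'
#' @param manifest a [PhantomManifest-class].
#' @param config generator configuration.
#' @return List of [TomatoSample-class], one per fruit x rotation, in
#'   manifest order.
#' @export
generateDataset <- function(manifest, config = phantomDefaults()) {
  fruits <- unique(manifest@records[, c("fruit_id", "label")])
  rotations <- seq_len(manifest@nRotations) - 1L
  out <- vector("list", nrow(fruits) * length(rotations))
  k <- 0L
  for (i in seq_len(nrow(fruits))) {
    fl <- fruitLevelDraws(manifest@seed, i, fruits$label[i], config)
    for (rot in rotations) {
      k <- k + 1L
      out[[k]] <- generateSample(
        fruits$label[i], fruits$fruit_id[i], rot, config,
        seed = recordSeed(manifest@seed, i, rot, 3L),
        quality = fl$quality, plateau = fl$plateau, redFrac = fl$redFrac)
    }
  }
  out
}

## Fruit-level draws shared by all rotations of fruit i.
fruitLevelDraws <- function(seed, fruitIndex, label, config) {
  quality <- generateQualityAttributes(label, 1L, config,
                                       seed = recordSeed(seed, fruitIndex,
                                                         0L, 1L))
  plateau <- withSeed(recordSeed(seed, fruitIndex, 0L, 2L),
                      drawPlateau(label, config))
  band <- config$image$redBand[[label]]
  redFrac <- withSeed(recordSeed(seed, fruitIndex, 0L, 6L),
                      stats::runif(1, band[1], band[2]))
  list(quality = quality, plateau = plateau, redFrac = redFrac)
}
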