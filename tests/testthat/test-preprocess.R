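test_that("segmentation thresholds, standardises and flags empty images", {
  # all-background image: warning, not an error
  flat <- array(40, c(20, 20, 3))
  expect_warning(seg <- segmentImage(flat), "empty foreground")
  expect_true(seg@empty)
  expect_false(any(foregroundMask(seg)))

  # bright disc on a dark background
  img <- array(10, c(60, 60, 3))
  xs <- matrix(seq_len(60), 60, 60, byrow = TRUE)
  ys <- matrix(seq_len(60), 60, 60)
  disc <- (xs - 30)^2 + (ys - 30)^2 <= 15^2
  for (ch in 1:3) { p <- img[, , ch]; p[disc] <- 200; img[, , ch] <- p }
  seg <- segmentImage(img)
  expect_equal(dim(imagePixels(seg)), c(150L, 150L, 3L))
  expect_equal(dim(foregroundMask(seg)), c(150L, 150L))
  # disc fills roughly pi/4 of its square bounding box after cropping
  expect_equal(mean(foregroundMask(seg)), pi / 4, tolerance = 0.08)

  # background is zeroed outside the mask
  px <- imagePixels(seg)
  expect_true(all(px[!array(foregroundMask(seg), dim(px))] == 0))
})

test_that("segmentation mask equals a per-pixel threshold oracle", {
  img <- renderTomatoImage("mature", seed = 31)
  seg <- segmentImage(img, outSize = NA)       # no resize: exact comparison
  oracle <- rgbToGray(img) > 50                # brute-force pixel scan
  expect_identical(unname(foregroundMask(seg)), unname(oracle))
  expect_equal(mean(foregroundMask(seg)), mean(oracle))
})

test_that("segmentation is idempotent on its own output", {
  for (s in c(32, 33)) {
    seg1 <- segmentImage(renderTomatoImage("semi_mature", seed = s))
    seg2 <- segmentImage(imagePixels(seg1))
    expect_identical(foregroundMask(seg2), foregroundMask(seg1))
  }
})

test_that("reference correction obeys its algebraic identities", {
  wl <- seq(400, 500, by = 1)
  rw <- 2000 + 3 * (wl - 400)
  rd <- 100 + 0.5 * (wl - 400)

  dark <- correctSpectrum(Spectrum(wl, rd, rw, rd))
  expect_equal(correctedSignal(dark), rep(0, length(wl)), tolerance = 1e-12)

  white <- correctSpectrum(Spectrum(wl, rw, rw, rd))
  expect_equal(correctedSignal(white), rep(1, length(wl)), tolerance = 1e-12)

  mid <- correctSpectrum(Spectrum(wl, (rw + rd) / 2, rw, rd))
  expect_equal(correctedSignal(mid), rep(0.5, length(wl)), tolerance = 1e-12)

  # affine invariance: common positive scaling leaves R unchanged
  raw <- rd + 0.37 * (rw - rd)
  a <- correctedSignal(correctSpectrum(Spectrum(wl, raw, rw, rd)))
  b <- correctedSignal(correctSpectrum(Spectrum(wl, 4.2 * raw, 4.2 * rw,
                                                4.2 * rd)))
  expect_equal(a, b, tolerance = 1e-12)

  # Rw = Rd channels are masked invalid and interpolated, not infinite
  rw2 <- rw; rw2[50] <- rd[50]
  expect_warning(cc <- correctSpectrum(Spectrum(wl, raw, rw2, rd)),
                 "invalid")
  expect_false(cc@valid[50])
  expect_true(all(is.finite(correctedSignal(cc))))

  # missing references / shape mismatches are rejected
  expect_error(correctSpectrum(list(a = 1)), "Spectrum")
  expect_error(Spectrum(wl, raw[-1], rw, rd), "length")
  expect_error(Spectrum(rev(wl), raw, rw, rd), "increasing")
})

test_that("Butterworth stage matches the analytic magnitude response", {
  # unit DC gain: a constant trace passes through unchanged
  const <- HapticTrace(rep(20, 1500))
  expect_equal(pressure(butterworthLowpass(const)), rep(20, 1500),
               tolerance = 1e-6)

  # single pass at the cutoff: 1/sqrt(1 + (f/fc)^(2n)) = 0.7071 at f = fc
  y10 <- pressure(butterworthLowpass(sineTrace(10), zeroPhase = FALSE))
  expect_equal(fittedAmplitude(y10, 10), 1 / sqrt(2), tolerance = 0.01)

  # forward-backward squares the response: 0.5 at the cutoff
  y10z <- pressure(butterworthLowpass(sineTrace(10)))
  expect_equal(fittedAmplitude(y10z, 10), 0.5, tolerance = 0.01)

  # deep in the stop band: 1/sqrt(1 + 4^8) at 40 Hz
  y40 <- pressure(butterworthLowpass(sineTrace(40), zeroPhase = FALSE))
  expect_equal(fittedAmplitude(y40, 40), 1 / sqrt(1 + 4^8),
               tolerance = 0.05)                # 5% relative
  expect_lt(fittedAmplitude(y40, 40), 5e-3)

  expect_error(butterworthLowpass(const, cutoff = 50), "Nyquist")
})

test_that("filtering removes the generator's super-cutoff vibration", {
  # energy above 10 Hz drops by at least 20 dB on phantom traces; a Hann
  # window suppresses the leakage of the non-periodic grip profile so the
  # comparison sees the vibration band, not windowing artifacts
  for (s in 1:3) {
    tr <- synthesizeHapticTrace("semi_mature", seed = 40 + s)
    raw <- pressure(tr)
    filt <- pressure(butterworthLowpass(tr))
    n <- length(raw)
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    freqs <- (seq_len(n) - 1) / n * 100
    keep <- freqs > 10 & freqs <= 50
    eRaw <- sum(Mod(stats::fft(raw * hann))[keep]^2)
    eFilt <- sum(Mod(stats::fft(filt * hann))[keep]^2)
    expect_gt(eRaw / eFilt, 100)               # >= 20 dB
  }
})

test_that("equatorial averaging matches its arithmetic oracle", {
  # noise-free plateaus 10/20/30/40 average to exactly 25
  traces <- lapply(c(10, 20, 30, 40), cleanTrace)
  expect_equal(averageEquatorialReadings(traces, filter = FALSE), 25,
               tolerance = 1e-9)
  # with the filter the ramp-corner ringing stays tiny
  expect_equal(averageEquatorialReadings(traces), 25, tolerance = 0.05)

  # four identical traces reduce to the single-trace summary
  four <- lapply(1:4, function(i) cleanTrace(33))
  expect_equal(averageEquatorialReadings(four, filter = FALSE),
               plateauPressure(four[[1]], filter = FALSE))

  # order invariance
  perm <- traces[c(3, 1, 4, 2)]
  expect_equal(averageEquatorialReadings(perm, filter = FALSE),
               averageEquatorialReadings(traces, filter = FALSE))

  expect_error(averageEquatorialReadings(traces[1:3]), "expected 4")
  short <- c(traces[1:3], list(HapticTrace(pressure(traces[[4]])[1:100])))
  expect_error(averageEquatorialReadings(short), "equal length")
})

test_that("firmness formula evaluates P = F / A", {
  expect_equal(firmnessFromForce(0), 0)
  # F = 1 N through the 8 mm tip: A = 5.0265e-5 m^2, P ~ 1.989e4 Pa
  expect_equal(firmnessFromForce(1), 1 / (pi * 0.004^2), tolerance = 1e-12)
  expect_equal(firmnessFromForce(1), 19894.37, tolerance = 1e-6)
  # linearity
  expect_equal(firmnessFromForce(2.4), 2.4 * firmnessFromForce(1))
  expect_error(firmnessFromForce(1, probeDiameter = 0), "positive")
  expect_error(firmnessFromForce(-1), "non-negative")
})
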