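#' @include utils.R
NULL

#' Default calibration of the synthetic tomato-phantom generator
#'
#' Returns the full parameter list of the generator. The class-conditional
#' targets (quality-attribute means, grip-pressure plateau ranges, spectral
#' peak positions and band ordering, red-fraction bands) reproduce the
#' published class statistics of the acquisition campaign the pipeline is
#' designed for; distribution shapes and spreads that are not published are
#' generator choices, documented in the methods vignette.
#'
#' Key entries:
#' \describe{
#'   \item{ssc / firmness}{class means (4.15/4.85/5.5 Brix and
#'     2.82/1.96/1.1 MPa for immature/semi-mature/mature) with truncated
#'     Gaussian spread. Heterogeneity categories borrow the mature
#'     (positive) or semi-mature (negatives) statistics.}
#'   \item{plateau}{grip plateau draw per label: uniform over 13--26 /
#'     26--46 / 52--65 kPa for mature/semi-mature/immature; Gaussian around
#'     29 kPa (negatives) and 13 kPa (positive) for the heterogeneity
#'     categories.}
#'   \item{spectrum}{350--1100 nm grid at 1 nm (751 points); Gaussian
#'     absorption features at 630/730/830/1070 nm over a smooth baseline
#'     with class amplitude scales ordering the 600--950 nm band mean
#'     mature > semi-mature > immature; template offsets of 5x / 1x the
#'     noise scale separate negative sample 1 / 2 from the positive
#'     category.}
#'   \item{haptic}{100 Hz x 15 s traces: approach to 3 s, smooth grip ramp
#'     to 5 s, plateau thereafter; additive gripper vibration in the
#'     20--40 Hz band plus white sensor noise.}
#'   \item{image}{render size, background gray level (< 50 so threshold-50
#'     segmentation isolates the fruit), red-fraction bands per label, and
#'     the fruit/unripe colours.}
#' }
#'
#' @return Nested list of generator parameters.
#' @examples
#' cfg <- phantomDefaults()
#' cfg$ssc$mean
#' @export
phantomDefaults <- function() {
  list(
    ssc = list(
      mean = c(immature = 4.15, semi_mature = 4.85, mature = 5.5,
               negative1 = 4.85, negative2 = 4.85, positive = 5.5),
      sd = 0.35),
    firmness = list(
      mean = c(immature = 2.82, semi_mature = 1.96, mature = 1.1,
               negative1 = 1.96, negative2 = 1.96, positive = 1.1),
      sd = 0.22),
    plateau = list(
      range = list(mature = c(13, 26), semi_mature = c(26, 46),
                   immature = c(52, 65)),
      hetero = list(negative1 = c(mean = 29, sd = 0.5),
                    negative2 = c(mean = 29, sd = 0.5),
                    positive = c(mean = 13, sd = 0.5))),
    haptic = list(
      sampleRate = 100, duration = 15,
      approachEnd = 3, rampEnd = 5,
      vibAmp = c(0.25, 0.55),       # kPa, uniform draw
      vibBand = c(20, 40),          # Hz
      whiteSd = 0.05),              # kPa
    spectrum = list(
      gridFrom = 350, gridTo = 1100, gridStep = 1,
      peaks = c(630, 730, 830, 1070),
      widths = c(20, 20, 20, 25),
      peakAmp = c(0.50, 0.38, 0.30, 0.22),
      classScale = c(immature = 0.35, semi_mature = 0.65, mature = 1,
                     negative1 = 1, negative2 = 1, positive = 1),
      heteroOffsetNoiseUnits = c(negative1 = 5, negative2 = 1, positive = 0),
      offsetBand = c(600, 950),
      noiseSd = 0.01,
      whiteLevel = 3500, darkLevel = 100),
    image = list(
      size = 160L, background = 20,
      ripeRGB = c(200, 40, 30), unripeRGB = c(60, 140, 50),
      colorJitter = 8,
      redBand = list(immature = c(0.0, 0.06), semi_mature = c(0.15, 0.85),
                     mature = c(0.925, 0.99), negative1 = c(0.96, 0.995),
                     negative2 = c(0.96, 0.995), positive = c(0.96, 0.995)),
      radiusFrac = c(0.40, 0.44),
      wiggleAmp = 0.02)
  )
}

spectrumGrid <- function(cfg) {
  s <- cfg$spectrum
  if (s$gridStep <= 0 || s$gridTo <= s$gridFrom)
    stop("wavelength grid must be strictly increasing")
  seq(s$gridFrom, s$gridTo, by = s$gridStep)
}
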