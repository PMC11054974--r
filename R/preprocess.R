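#' @include phantom-io.R
NULL

#' Threshold segmentation and standardisation of a fruit image
#'
#' Converts the image to grayscale with standard luma weights
#' (0.299/0.587/0.114), marks pixels strictly above the fixed threshold
#' (default 50) as foreground, zeroes the background, crops to the
#' foreground bounding box, and rescales it (anisotropically if the box is
#' not square) to `outSize x outSize` (default 150; pixels bilinearly, mask
#' by nearest neighbour, with resized background re-zeroed). When the crop
#' already has the target size the resize is skipped, which makes the
#' operation exactly idempotent on its own output for blob-shaped
#' foregrounds that fill their bounding box edges. An image with
#' no foreground pixel raises a warning (not an error) and returns an
#' all-background result flagged `empty`.
#'
#' @param image H x W x 3 numeric array on the 0--255 scale.
#' @param threshold gray-level threshold (default 50).
#' @param outSize output side length in pixels (default 150); `NA` skips
#'   cropping and resizing entirely (useful for mask-level comparisons).
#' @return A [SegmentedImage-class].
#' @examples
#' img <- renderTomatoImage("mature", seed = 1)
#' seg <- segmentImage(img)
#' dim(imagePixels(seg))  # 150 150 3
#' @export
segmentImage <- function(image, threshold = 50, outSize = 150L) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 array")
  gray <- rgbToGray(image)
  mask <- gray > threshold
  if (!any(mask)) {
    warning("empty foreground: no pixel above threshold ", threshold)
    sz <- if (is.na(outSize)) d[1:2] else c(outSize, outSize)
    return(new("SegmentedImage",
               pixels = array(0, c(sz[1], sz[2], 3)),
               mask = matrix(FALSE, sz[1], sz[2]), empty = TRUE))
  }
  px <- image
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[!mask] <- 0
    px[, , ch] <- plane
  }
  if (is.na(outSize))
    return(new("SegmentedImage", pixels = px, mask = mask, empty = FALSE))
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  px <- px[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  mask <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  res <- resizeMasked(px, mask, outSize, outSize)
  new("SegmentedImage", pixels = res$pixels, mask = res$mask,
      empty = FALSE)
}

#' Black-and-white correction of a raw spectrum
#'
#' Applies the reference correction R = (Rraw - Rd) / (Rw - Rd) elementwise.
#' Channels where the white and dark references coincide are marked invalid
#' (the correction is undefined there) rather than returned as infinities;
#' invalid channels are filled by linear interpolation from their valid
#' neighbours, with a warning. The correction is invariant to scaling all
#' three inputs by a common positive factor.
#'
#' @param spectrum a [Spectrum-class] with raw signal and both references.
#' @return The spectrum with `rCorrected` and the validity mask populated.
#' @examples
#' sp <- synthesizeSpectrum("immature", seed = 2)
#' spc <- correctSpectrum(sp)
#' range(correctedSignal(spc))
#' @export
correctSpectrum <- function(spectrum) {
  if (!is(spectrum, "Spectrum"))
    stop("correctSpectrum expects a Spectrum object")
  rw <- spectrum@rWhite
  rd <- spectrum@rDark
  rr <- spectrum@rRaw
  if (!length(rw) || !length(rd))
    stop("white and dark references are required")
  denom <- rw - rd
  valid <- denom != 0
  r <- rep(NA_real_, length(rr))
  r[valid] <- (rr[valid] - rd[valid]) / denom[valid]
  if (any(!valid)) {
    warning(sum(!valid), " channel(s) have identical white and dark ",
            "references; marked invalid and interpolated")
    if (sum(valid) >= 2L) {
      r[!valid] <- stats::approx(spectrum@wavelengths[valid], r[valid],
                                 xout = spectrum@wavelengths[!valid],
                                 rule = 2)$y
    } else r[!valid] <- 0
  }
  spectrum@rCorrected <- r
  spectrum@valid <- valid
  validObject(spectrum)
  spectrum
}

#' Zero-phase Butterworth low-pass filter for grip traces
#'
#' Removes mechanical-vibration noise from a pressure trace with a
#' Butterworth low-pass of the given order (default 4) and cutoff (default
#' 10 Hz), applied forward-backward (zero phase) by default so the plateau
#' onset is not delayed. A single forward pass (`zeroPhase = FALSE`) has the
#' textbook magnitude response 1/sqrt(1 + (f/fc)^(2n)): -3 dB at the
#' cutoff; the forward-backward application squares the magnitude response.
#'
#' @param trace a [HapticTrace-class] (or numeric vector, with `rate`).
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param order filter order.
#' @param zeroPhase forward-backward application (default TRUE).
#' @param rate sample rate when `trace` is a bare numeric vector.
#' @return A filtered [HapticTrace-class] of the same length.
#' @examples
#' tr <- synthesizeHapticTrace("mature", seed = 4)
#' f <- butterworthLowpass(tr)
#' @export
butterworthLowpass <- function(trace, cutoff = 10, order = 4,
                               zeroPhase = TRUE, rate = 100) {
  if (is(trace, "HapticTrace")) {
    x <- trace@pressure
    rate <- trace@sampleRate
  } else x <- as.numeric(trace)
  nyq <- rate / 2
  if (cutoff >= nyq)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  y <- if (zeroPhase)
    reflectFiltfilt(bf, x)
  else
    as.numeric(signal::filter(bf, x))
  HapticTrace(y, rate)
}

## Forward-backward filtering with odd-reflection end padding, so edges see
## a continuation of the signal instead of an implicit jump to zero.
reflectFiltfilt <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 60L)
  head_ <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_ <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(head_, x, tail_)
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[pad + seq_len(n)]
}

#' Plateau pressure of a grip trace
#'
#' Summarises a trace by its stable grip level: after (optional) zero-phase
#' low-pass filtering, the plateau segment is taken as the span from the
#' first to the last sample at or above the trace's upper quartile, and the
#' summary is the mean over that span. For the standard
#' approach/ramp/plateau profile this recovers the plateau level robustly
#' regardless of ramp length.
#'
#' @param trace a [HapticTrace-class].
#' @param filter apply [butterworthLowpass()] first (default TRUE).
#' @param cutoff,order filter settings.
#' @return Plateau level in kPa.
#' @export
plateauPressure <- function(trace, filter = TRUE, cutoff = 10, order = 4) {
  if (!is(trace, "HapticTrace"))
    trace <- HapticTrace(trace)
  x <- if (filter) pressure(butterworthLowpass(trace, cutoff, order))
       else pressure(trace)
  q3 <- stats::quantile(x, 0.75, names = FALSE)
  hi <- which(x >= q3)
  mean(x[hi[1]:hi[length(hi)]])
}

#' Average the four equatorial grip readings of a fruit
#'
#' The acquisition protocol measures each fruit at four equatorial points
#' (rotating 90 degrees); the fruit's overall pressure value is the mean of
#' the four per-trace plateau summaries. Traces are filtered before
#' summarising; the result is invariant to trace order.
#'
#' @param traces list of [HapticTrace-class] objects (default expectation:
#'   4, one per equatorial point), all the same length.
#' @param nExpected expected number of traces (default 4).
#' @param ... passed to [plateauPressure()].
#' @return Mean plateau pressure in kPa.
#' @export
averageEquatorialReadings <- function(traces, nExpected = 4L, ...) {
  if (!is.list(traces))
    stop("traces must be a list of HapticTrace objects")
  if (length(traces) != nExpected)
    stop("expected ", nExpected, " traces, got ", length(traces))
  lens <- vapply(traces, function(tr) length(pressure(tr)), numeric(1))
  if (length(unique(lens)) != 1L)
    stop("all traces must have equal length; got lengths ",
         paste(lens, collapse = ", "))
  mean(vapply(traces, plateauPressure, numeric(1), ...))
}

#' Firmness from penetrometer force
#'
#' Firmness is defined as force per unit contact area, P = F / A, with the
#' plunger contact area A = pi (d/2)^2 of the 8 mm tip.
#'
#' @param force force in newtons (>= 0).
#' @param probeDiameter plunger tip diameter in metres (default 0.008).
#' @return Pressure in Pa.
#' @examples
#' firmnessFromForce(1)          # ~1.989e4 Pa for the 8 mm tip
#' @export
firmnessFromForce <- function(force, probeDiameter = 0.008) {
  if (probeDiameter <= 0)
    stop("probe diameter must be positive")
  if (any(force < 0))
    stop("force must be non-negative")
  force / (pi * (probeDiameter / 2)^2)
}

#' Preprocess one acquisition triplet for the extractors
#'
#' Bundles the three preprocessing steps: segmentation to 150 x 150,
#' black-and-white spectral correction, and zero-phase Butterworth
#' filtering of the grip trace.
#'
#' @param sample a [TomatoSample-class].
#' @param outSize segmentation output size.
#' @param cutoff,order haptic filter settings.
#' @return List with `image` ([SegmentedImage-class]), `spectrum`
#'   (corrected [Spectrum-class]) and `haptic` (filtered
#'   [HapticTrace-class]).
#' @export
preprocessSample <- function(sample, outSize = 150L, cutoff = 10,
                             order = 4) {
  list(image = segmentImage(sample@image, outSize = outSize),
       spectrum = correctSpectrum(sample@spectrum),
       haptic = butterworthLowpass(sample@haptic, cutoff, order))
}
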