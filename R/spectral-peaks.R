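#' @include preprocess.R
NULL

#' Locate an absorption-feature wavelength in a (mean) corrected spectrum
#'
#' Finds the local extremum inside a wavelength window and refines it with
#' a quadratic vertex fit over a small neighbourhood, the usual way a peak
#' position is read off a noisy sampled spectrum. On the default 1 nm grid
#' the returned position is snapped back to the grid.
#'
#' @param values corrected spectrum (or a mean of corrected spectra).
#' @param wl wavelength grid in nm.
#' @param window length-2 search window in nm (e.g. `c(580, 680)`).
#' @param fitHalfWidth half-width in nm of the quadratic fit around the
#'   raw argmax (default 15).
#' @param snapToGrid round the refined position to the nearest grid point.
#' @return Peak wavelength in nm.
#' @examples
#' sp <- correctSpectrum(synthesizeSpectrum("mature", noiseSd = 0))
#' peakWavelength(correctedSignal(sp), wavelengths(sp), c(580, 680))  # 630
#' @export
peakWavelength <- function(values, wl, window = c(580, 680),
                           fitHalfWidth = 15, snapToGrid = TRUE) {
  if (length(values) != length(wl))
    stop("values and wl must have equal length")
  inWin <- which(wl >= window[1] & wl <= window[2])
  if (!length(inWin))
    stop("empty search window")
  i0 <- inWin[which.max(values[inWin])]
  near <- which(abs(wl - wl[i0]) <= fitHalfWidth)
  if (length(near) >= 5L) {
    x <- wl[near] - wl[i0]
    fit <- stats::lm(values[near] ~ x + I(x^2))
    a <- stats::coef(fit)
    if (is.finite(a[3]) && a[3] < 0) {
      vertex <- wl[i0] - a[2] / (2 * a[3])
      if (vertex >= window[1] && vertex <= window[2]) {
        if (snapToGrid)
          return(wl[which.min(abs(wl - vertex))])
        return(as.numeric(vertex))
      }
    }
  }
  wl[i0]
}
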