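#' @include AllClasses.R
NULL

## Evaluate expr under a temporary RNG seed, restoring the caller's RNG
## state afterwards. seed = NULL leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed))
    return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-record sub-seed derived from a dataset seed. Kept well
## below .Machine$integer.max.
recordSeed <- function(seed, fruitIndex, rotation, channel = 0L) {
  base <- as.numeric(seed) %% 1000003
  s <- (base * 1009 + fruitIndex * 7 + rotation * 3 + channel) %% 2000000011
  as.integer(s)
}

#' Standard-luma grayscale conversion
#'
#' Converts an 8-bit RGB array to grayscale with the usual luma weights
#' 0.299 R + 0.587 G + 0.114 B.
#'
#' @param image H x W x 3 numeric array on the 0--255 scale.
#' @return H x W numeric matrix.
#' @export
rgbToGray <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 array")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Red-surface fraction of an image
#'
#' Rule-based red test used to verify the stage definitions on rendered
#' phantoms: a foreground pixel counts as red when its red channel exceeds
#' its green channel by at least `margin` (8-bit units). The foreground is
#' either a supplied mask or all pixels whose luma exceeds `threshold`.
#'
#' @param image H x W x 3 array, 0--255.
#' @param mask optional logical foreground mask; when NULL, luma > threshold.
#' @param margin red-over-green margin (default 30).
#' @param threshold luma threshold used when `mask` is NULL (default 50).
#' @return Fraction of foreground pixels classified red (NaN when the
#'   foreground is empty).
#' @export
redFraction <- function(image, mask = NULL, margin = 30, threshold = 50) {
  if (is.null(mask))
    mask <- rgbToGray(image) > threshold
  red <- (image[, , 1] - image[, , 2]) >= margin
  if (!any(mask)) return(NaN)
  mean(red[mask])
}

## Bilinear resize of an H x W (x C) numeric array to h x w. Maps output
## pixel centres to input pixel centres (align-centres convention). When the
## target equals the source size this is the identity and the input is
## returned unchanged.
resizeBilinear <- function(x, h, w) {
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  if (d[1] == h && d[2] == w)
    return(x)
  xa <- array(x, d)
  sy <- d[1] / h
  sx <- d[2] / w
  yc <- (seq_len(h) - 0.5) * sy + 0.5   # fractional source row coords
  xc <- (seq_len(w) - 0.5) * sx + 0.5
  y0 <- pmin(pmax(floor(yc), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(xc), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(yc - y0, 0), 1)
  wx <- pmin(pmax(xc - x0, 0), 1)
  out <- array(0, c(h, w, d[3]))
  WY <- matrix(wy, h, w)
  WX <- matrix(wx, h, w, byrow = TRUE)
  for (c in seq_len(d[3])) {
    ch <- xa[, , c]
    a <- ch[cbind(rep(y0, w), rep(x0, each = h))]
    b <- ch[cbind(rep(y0, w), rep(x1, each = h))]
    cc <- ch[cbind(rep(y1, w), rep(x0, each = h))]
    dd <- ch[cbind(rep(y1, w), rep(x1, each = h))]
    A <- matrix(a, h, w); B <- matrix(b, h, w)
    C <- matrix(cc, h, w); D <- matrix(dd, h, w)
    out[, , c] <- (1 - WY) * ((1 - WX) * A + WX * B) +
      WY * ((1 - WX) * C + WX * D)
  }
  if (length(dim(x)) == 2L) out[, , 1] else out
}

## Mask-aware resize: pixels are resampled by normalised-convolution
## bilinear interpolation (foreground values are weighted only by
## foreground support, so boundary pixels never blend with the zeroed
## background and interpolated values stay inside the foreground value
## range), the mask by nearest neighbour, and background is re-zeroed.
resizeMasked <- function(px, mask, h, w) {
  if (nrow(mask) == h && ncol(mask) == w)
    return(list(pixels = px, mask = mask))
  m01 <- mask * 1
  num <- resizeBilinear(px * array(m01, dim(px)), h, w)
  den <- resizeBilinear(m01, h, w)
  mout <- resizeNearest(mask, h, w)
  out <- array(0, c(h, w, dim(px)[3]))
  ok <- mout & den > 0
  for (ch in seq_len(dim(px)[3])) {
    plane <- num[, , ch]
    plane[ok] <- plane[ok] / den[ok]
    plane[!ok] <- 0
    out[, , ch] <- plane
  }
  list(pixels = out, mask = mout)
}

## Nearest-neighbour resize (used for masks).
resizeNearest <- function(x, h, w) {
  d <- dim(x)
  if (d[1] == h && d[2] == w)
    return(x)
  yi <- pmin(pmax(ceiling((seq_len(h) - 0.5) * d[1] / h), 1), d[1])
  xi <- pmin(pmax(ceiling((seq_len(w) - 0.5) * d[2] / w), 1), d[2])
  x[yi, xi, drop = FALSE]
}

## Largest-remainder apportionment of n items into fractions.
apportion <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
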