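#' @useDynLib linecooc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate conventions used throughout the package
# --------------------------------------------------
# Images are numeric matrices indexed [row, col] with row 1 at the top
# (raster storage).  All geometry, however, lives in the mathematical frame
# with x pointing right and y pointing up: a pixel at [r, c] of an
# nr-row image has math coordinates (x, y) = (c, nr + 1 - r).  Angles are
# measured counter-clockwise from the +x axis.  The conversion happens in
# exactly two places: `px_to_xy()` / `xy_to_px()`.

#' Orientation bin angles
#'
#' Angles of the `n_theta` pi-periodic orientation bins,
#' `theta_k = -pi/2 + (k-1) * pi / n_theta`.
#'
#' @param n_theta number of orientation bins on `[-pi/2, pi/2)`.
#' @return numeric vector of length `n_theta`.
#' @export
theta_bins <- function(n_theta) {
  stopifnot(is.numeric(n_theta), length(n_theta) == 1L, n_theta >= 1)
  -pi / 2 + (seq_len(n_theta) - 1L) * pi / n_theta
}

#' Convert raster pixel indices to math-frame coordinates
#'
#' @param r,c row and column indices (1-based).
#' @param nrow number of image rows.
#' @return two-column matrix of (x, y).
#' @export
px_to_xy <- function(r, c, nrow) cbind(x = c, y = nrow + 1 - r)

#' Convert math-frame coordinates to raster pixel indices
#'
#' @param x,y math-frame coordinates.
#' @param nrow number of image rows.
#' @return two-column matrix of (r, c).
#' @export
xy_to_px <- function(x, y, nrow) cbind(r = nrow + 1 - y, c = x)

# DFT angular frequencies (rad/sample) in R's fft ordering.
fft_freqs <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  2 * pi * k / n
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Move the zero-offset element to the center of an odd-sized matrix
# (and back with `ifftshift2`).
fftshift2 <- function(x) {
  sh <- function(n) ((seq_len(n) - 1 - floor(n / 2)) %% n) + 1
  x[sh(nrow(x)), sh(ncol(x)), drop = FALSE]
}
ifftshift2 <- function(x) {
  sh <- function(n) ((seq_len(n) - 1 + floor(n / 2)) %% n) + 1
  x[sh(nrow(x)), sh(ncol(x)), drop = FALSE]
}

# Reflective (mirror, no edge repeat would be 'symmetric'; we use edge-
# inclusive reflection) padding by w pixels on each side.
reflect_pad <- function(img, w) {
  nr <- nrow(img); nc <- ncol(img)
  if (w >= nr || w >= nc) stop("padding exceeds image size")
  ridx <- c(rev(seq_len(w) + 1L), seq_len(nr), nr - seq_len(w))
  cidx <- c(rev(seq_len(w) + 1L), seq_len(nc), nc - seq_len(w))
  img[ridx, cidx, drop = FALSE]
}

# Gaussian blur with reflective boundary via FFT on the padded grid.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  w <- min(ceiling(4 * sigma), nrow(img) - 1L, ncol(img) - 1L)
  p <- reflect_pad(img, w)
  u <- fft_freqs(ncol(p)); v <- fft_freqs(nrow(p))
  g <- exp(-outer(v^2, u^2, `+`) * sigma^2 / 2)
  out <- Re(ifft2(fft2(p) * g))
  out[(w + 1):(w + nrow(img)), (w + 1):(w + ncol(img)), drop = FALSE]
}

#' Rotate an image about its center (math-frame CCW angle)
#'
#' Bilinear resampling; pixels mapped from outside the source are filled
#' with `fill`.  Used mainly as an independent oracle when testing rotation
#' covariance of the orientation-score transform.
#'
#' @param img numeric matrix.
#' @param angle rotation angle in radians, counter-clockwise in the math
#'   frame (x right, y up).
#' @param fill value for samples falling outside the image.
#' @return rotated matrix of the same size.
#' @export
rotate_image <- function(img, angle, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  co <- cos(angle); si <- sin(angle)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  # math offsets of each target pixel
  x <- g$c - cc; y <- cr - g$r
  # inverse rotation to find the source sample
  xs <- co * x + si * y
  ys <- -si * x + co * y
  sc <- xs + cc; sr <- cr - ys
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- rep(fill, length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  matrix(out, nr, nc)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Cardinal B-spline of order n (degree n), support [-(n+1)/2, (n+1)/2].
bspline_cardinal <- function(x, n) {
  stopifnot(n >= 0)
  s <- numeric(length(x))
  xx <- x + (n + 1) / 2
  for (k in 0:(n + 1)) {
    s <- s + (-1)^k * choose(n + 1, k) * pmax(xx - k, 0)^n
  }
  if (n == 0) return(as.numeric(x >= -0.5 & x < 0.5))
  s / factorial(n)
}
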