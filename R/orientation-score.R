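#' Lift an image to an orientation score
#'
#' Correlates the image with the complex-conjugated rotated cake wavelets,
#' producing a complex score on positions x orientations.  The real part
#' acts as a ridge detector: dark lines on a bright background yield large
#' negative responses at their orientation.  Borders are handled by
#' reflective padding.
#'
#' @param image numeric matrix (intensities, any units; finite).
#' @param wavelets a [make_cake_wavelets()] stack; its size must not
#'   exceed either image dimension.
#' @return an `orientation_score` object: complex array
#'   `nrow x ncol x n_theta` with attributes `theta_bins`.
#' @export
orientation_score <- function(image, wavelets) {
  stopifnot(inherits(wavelets, "cake_wavelets"))
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image must contain finite values")
  s <- wavelets$size
  if (s > nrow(image) || s > ncol(image))
    stop("wavelet size exceeds image dimensions")
  w <- (s - 1L) %/% 2L
  pad <- reflect_pad(image, w)
  L1 <- nrow(pad); L2 <- ncol(pad)
  Fpad <- fft2(pad)
  n_theta <- wavelets$n_theta
  out <- array(0i, c(nrow(image), ncol(image), n_theta))
  for (k in seq_len(n_theta)) {
    psi <- wavelets$filters[, , k]
    # place psi(t) at index (t mod L) + 1 so that
    # corr(x) = sum_t conj(psi(t)) f(x + t)
    kern <- matrix(0i, L1, L2)
    idx_r <- ((seq_len(s) - 1L - w) %% L1) + 1L
    idx_c <- ((seq_len(s) - 1L - w) %% L2) + 1L
    kern[idx_r, idx_c] <- psi
    corr <- ifft2(Fpad * Conj(fft2(kern)))
    out[, , k] <- corr[(w + 1):(w + nrow(image)),
                       (w + 1):(w + ncol(image))]
  }
  structure(out, theta_bins = wavelets$theta_bins,
            class = "orientation_score")
}

#' Dominant orientation per pixel
#'
#' At every pixel selected by `mask`, picks the orientation bin maximizing
#' the negated real part of the score (vessels are darker than background,
#' hence respond with large negative real values).  Ties are broken toward
#' the lowest bin index.
#'
#' @param score an [orientation_score()] result.
#' @param mask logical matrix of the same spatial size.
#' @return an `orientation_map`: list with `angle_index` (integer matrix,
#'   bins 1..n_theta, NA off the mask), `defined_mask`, and `theta_bins`.
#' @export
dominant_orientations <- function(score, mask) {
  stopifnot(inherits(score, "orientation_score"))
  d <- dim(score)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), d[1:2]))
    stop("mask shape does not match score")
  mask <- mask > 0 & !is.na(mask)
  idx <- which(mask)
  angle_index <- matrix(NA_integer_, d[1], d[2])
  if (length(idx)) {
    resp <- matrix(0, length(idx), d[3])
    for (k in seq_len(d[3])) {
      slice <- Re(score[, , k])
      resp[, k] <- -slice[idx]
    }
    angle_index[idx] <- max.col(resp, ties.method = "first")
  }
  structure(list(angle_index = angle_index, defined_mask = mask,
                 theta_bins = attr(score, "theta_bins")),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("orientation map: %d defined pixels, %d bins\n",
              sum(x$defined_mask), length(x$theta_bins)))
  invisible(x)
}
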