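#' Construct a stack of bi-directional cake wavelets
#'
#' Builds `n_theta` orientation-selective filters in the Fourier domain.
#' The frequency plane is divided into `2 * n_theta` angular wedges whose
#' profiles are shifted cardinal B-splines (a partition of unity on the
#' circle); antipodal wedges are summed, which makes every filter
#' pi-periodic (bi-directional, i.e. sensitive to lines without polarity).
#' The radial profile is 1 minus a Gaussian DC notch, multiplied by a
#' smooth taper that rolls off from `nyquist_taper` times the Nyquist
#' frequency.  Consequently the summed spectra of the stack equal 1 on the
#' "pass annulus" between the DC-exclusion radius and the taper onset, so
#' the stack tiles the frequency plane there, and the response of every
#' filter to a constant image is zero.
#'
#' @param n_theta number of orientations on `[-pi/2, pi/2)` (>= 1).
#' @param size odd spatial filter size in pixels.
#' @param angular_order order of the B-spline angular profile (default 3).
#' @param nyquist_taper onset of the high-frequency roll-off as a fraction
#'   of the Nyquist frequency, in (0, 1].
#' @param dc_sigma standard deviation (rad/px) of the Gaussian DC notch.
#' @return an object of class `cake_wavelets`: list with `filters` (a
#'   `size x size x n_theta` complex array; filter k detects lines at
#'   `theta_bins[k]`), `n_theta`, `theta_bins`, `size`, `pass_band` (inner
#'   and outer radius, rad/px, of the annulus on which the spectra sum
#'   to 1), and the construction parameters.
#' @export
make_cake_wavelets <- function(n_theta, size, angular_order = 3,
                               nyquist_taper = 0.9, dc_sigma = 0.04 * pi) {
  if (!is.numeric(n_theta) || length(n_theta) != 1L || n_theta < 1)
    stop("n_theta must be a positive integer")
  n_theta <- as.integer(n_theta)
  if (size %% 2 == 0) stop("filter size must be odd")
  if (nyquist_taper <= 0 || nyquist_taper > 1)
    stop("nyquist_taper must lie in (0, 1]")

  u <- fft_freqs(size)               # x (col) frequency
  v <- fft_freqs(size)               # row frequency; math y freq = -v
  U <- matrix(u, size, size, byrow = TRUE)
  V <- matrix(v, size, size)
  rho <- sqrt(U^2 + V^2)
  phi <- atan2(-V, U)                # math-frame angle of the frequency

  # radial profile: DC notch times Nyquist roll-off
  notch <- 1 - exp(-rho^2 / (2 * dc_sigma^2))
  rho0 <- nyquist_taper * pi
  wtap <- (pi - rho0) / 3
  taper <- ifelse(rho <= rho0 | wtap == 0, 1,
                  exp(-(rho - rho0)^2 / (2 * wtap^2)))
  radial <- notch * taper
  radial[1, 1] <- 0                  # DC removed exactly

  s_theta <- pi / n_theta            # wedge spacing on the full circle
  thetas <- theta_bins(n_theta)
  filters <- array(0i, c(size, size, n_theta))
  spectra <- array(0, c(size, size, n_theta))
  for (k in seq_len(n_theta)) {
    centre <- thetas[k] + pi / 2     # lines at theta -> energy at theta+pi/2
    ang <- 0
    for (cen in c(centre, centre + pi)) {
      dphi <- (phi - cen + pi) %% (2 * pi) - pi
      for (m in -3:3) {
        ang <- ang + bspline_cardinal((dphi + 2 * pi * m) / s_theta,
                                      angular_order)
      }
    }
    spec <- radial * ang
    spectra[, , k] <- spec
    filters[, , k] <- fftshift2(ifft2(spec))
  }

  structure(list(
    filters = filters,
    n_theta = n_theta,
    theta_bins = thetas,
    size = as.integer(size),
    angular_order = angular_order,
    nyquist_taper = nyquist_taper,
    dc_sigma = dc_sigma,
    pass_band = c(dc_sigma * sqrt(2 * log(1e7)), rho0)
  ), class = "cake_wavelets")
}

#' Summed Fourier spectra of a wavelet stack
#'
#' Recomputes the spectra from the stored spatial filters and sums them
#' over orientation.  On the pass annulus the result equals 1 (partition
#' of unity of the cake decomposition).
#'
#' @param wavelets a `cake_wavelets` object.
#' @return list with `total` (real matrix, fft frequency ordering), `rho`
#'   (matrix of radial frequencies) and `pass_band`.
#' @export
wavelet_partition <- function(wavelets) {
  stopifnot(inherits(wavelets, "cake_wavelets"))
  size <- wavelets$size
  tot <- matrix(0, size, size)
  for (k in seq_len(wavelets$n_theta)) {
    tot <- tot + Re(fft2(ifftshift2(wavelets$filters[, , k])))
  }
  u <- fft_freqs(size)
  rho <- sqrt(outer(u^2, u^2, `+`))
  list(total = tot, rho = rho, pass_band = wavelets$pass_band)
}

#' @export
print.cake_wavelets <- function(x, ...) {
  cat(sprintf(
    "cake wavelet stack: %d orientations, %dx%d px, B-spline order %d\n",
    x$n_theta, x$size, x$size, x$angular_order))
  cat(sprintf("pass annulus: [%.3f, %.3f] rad/px\n",
              x$pass_band[1], x$pass_band[2]))
  invisible(x)
}
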