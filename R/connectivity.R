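# The direction-process connectivity model.
#
# Mumford's direction process travels at unit speed along its current
# orientation while the orientation diffuses with coefficient D33; killing
# at rate alpha makes the travel time Exp(alpha).  The time-integrated law
# (the resolvent) is the probabilistic connectivity kernel; symmetrizing
# over direction reversal and a pi-shift carries it to the projective line
# bundle where it is comparable with line co-occurrence statistics.

#' Parameters of the direction process
#'
#' @param alpha decay rate (1/px of travel); the expected lifetime is
#'   `1/alpha` pixels.
#' @param D33 angular diffusion constant (rad^2/px); `sigma = sqrt(2 D33)`.
#' @param blur_s spatial Gaussian sigma (px) emulating the one-pixel bin
#'   of the statistical kernel.
#' @return a `direction_process_params` object.
#' @export
direction_process_params <- function(alpha, D33, blur_s = 0.5) {
  if (alpha <= 0) stop("alpha must be positive")
  if (D33 < 0) stop("D33 must be nonnegative")
  structure(list(alpha = alpha, D33 = D33, sigma = sqrt(2 * D33),
                 blur_s = blur_s), class = "direction_process_params")
}

#' @export
print.direction_process_params <- function(x, ...) {
  cat(sprintf("direction process: alpha=%g (E[T]=%.1f px), D33=%g (sigma=%.4f), blur_s=%g\n",
              x$alpha, 1 / x$alpha, x$D33, x$sigma, x$blur_s))
  invisible(x)
}

new_resolvent_kernel <- function(values, params, n_theta, d,
                                 mass_precrop = NA_real_,
                                 cropped_mass = NA_real_, source = "fourier") {
  structure(values, params = params, d = as.integer(d),
            n_theta = as.integer(n_theta),
            theta_samples = -pi + (seq_len(2 * n_theta) - 1) * pi / n_theta,
            mass_precrop = mass_precrop, cropped_mass = cropped_mass,
            source = source, class = "resolvent_kernel")
}

#' @export
print.resolvent_kernel <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "direction-process resolvent (%s): d=%d, 2*n_theta=%d, alpha=%g, D33=%g, mass %.6g\n",
    attr(x, "source"), attr(x, "d"), dim(x)[3], p$alpha, p$D33, sum(x)))
  invisible(x)
}

#' Numeric Fokker-Planck resolvent of the direction process
#'
#' Solves the resolvent equation `(alpha I - A) R = alpha delta_e` with
#' generator `A = -cos(theta) dx - sin(theta) dy + D33 dtheta^2` by a 2D
#' discrete Fourier transform in space on a `pad_factor`-enlarged periodic
#' domain and, per spatial frequency, a dense solve over `2 n_theta`
#' periodic theta samples of `[-pi, pi)`.  A slight spatial Gaussian blur
#' (`params$blur_s`) emulates the one-pixel bin of the statistical kernel.
#' The result is cropped to the (2d+1)^2 spatial window; the cropped-away
#' mass is recorded and the kernel renormalized to total mass 1.
#'
#' @param params a [direction_process_params()] object.
#' @param d spatial half-width of the output grid (px).
#' @param n_theta number of pi-periodic orientation bins; the kernel is
#'   computed on `2 n_theta` samples of the full circle.
#' @param pad_factor periodic domain enlargement factor (>= 1) suppressing
#'   wrap-around of long-lived paths.
#' @param n_harmonics theta-Fourier truncation order; angular diffusion
#'   is exact in this basis and every output value is the exact integral
#'   of the truncated series over its one-pixel theta bin.
#' @param supersample spatial solution grid refinement; with the default 2
#'   the pixel-box window vanishes at the (doubled) Nyquist frequency, so
#'   band-limiting the sharp origin peak causes almost no ringing.
#' @return a `resolvent_kernel`: array (2d+1) x (2d+1) x 2 n_theta indexed
#'   [x, y, theta] with attributes `mass_precrop`, `cropped_mass`, `params`.
#' @export
fp_resolvent_numeric <- function(params, d, n_theta, pad_factor = 2,
                                 n_harmonics = 96, supersample = 2) {
  stopifnot(inherits(params, "direction_process_params"),
            d >= 1, n_theta >= 1, pad_factor >= 1, supersample >= 1)
  ss <- as.integer(supersample)
  P <- as.integer(2 * ceiling(pad_factor) * d + 1)  # physical period (px)
  N <- ss * P                                       # fine samples, 1/ss px
  Nt <- 2L * as.integer(n_theta)
  if (params$D33 == 0) {
    # Deterministic limit: motion never turns, so all mass lies at
    # theta = 0 with spatial law alpha exp(-alpha x) delta(y) for x > 0.
    # Bin-integrated (and blur_s-smoothed) values factorize and have
    # closed forms, so this case is built exactly in real space.  (The
    # harmonic expansion is unusable here: with a flat diagonal its
    # truncated recurrence has marginally stable roots.)
    a <- params$alpha; sb <- params$blur_s
    Fcdf <- if (sb > 0) {
      # cdf of the exponential ray convolved with a Gaussian
      function(s) stats::pnorm(s / sb) -
        exp(a^2 * sb^2 / 2 - a * s) * stats::pnorm((s - a * sb^2) / sb)
    } else {
      function(s) ifelse(s > 0, 1 - exp(-a * s), 0)
    }
    hx_at <- function(x) Fcdf(x + 0.5) - Fcdf(x - 0.5)
    hy_at <- if (sb > 0) {
      function(y) stats::pnorm((y + 0.5) / sb) - stats::pnorm((y - 0.5) / sb)
    } else {
      function(y) as.numeric(y == 0)
    }
    S <- 2L * d + 1L
    out <- array(0, c(S, S, Nt))
    out[, , n_theta + 1L] <- outer(hx_at(-d:d), hy_at(-d:d))
    mass_precrop <- 1       # the continuum law is exactly normalized
    cropped <- mass_precrop - sum(out)
    out <- out / sum(out)
    return(new_resolvent_kernel(out, params, n_theta, d,
                                mass_precrop = mass_precrop,
                                cropped_mass = cropped))
  }
  cube <- resolvent_fourier_cpp(params$alpha, params$D33, N, n_theta,
                                as.integer(n_harmonics), ss)
  w <- fft_freqs(N) * ss                            # rad/px on the fine grid
  # pixel-bin integration (box window) times the slight Gaussian blur
  sx <- ifelse(w == 0, 1, sin(w / 2) / (w / 2))
  blur <- outer(sx, sx)
  if (params$blur_s > 0)
    blur <- blur * exp(-outer(w^2, w^2, `+`) * params$blur_s^2 / 2)
  S <- 2L * d + 1L
  keep <- (((-d:d) %% P) * ss) + 1L    # fine indices of integer offsets
  allint <- (ss * (0:(P - 1))) + 1L
  out <- array(0, c(S, S, Nt))
  mass_precrop <- 0
  for (t in seq_len(Nt)) {
    slice <- Re(ifft2(cube[, , t] * blur)) * ss^2
    mass_precrop <- mass_precrop + sum(slice[allint, allint])
    out[, , t] <- slice[keep, keep]
  }
  # Truncating the theta-Fourier series (and band-limiting the sharp
  # origin peak) leaves small negative Gibbs lobes; they are clamped as
  # long as they carry only a small fraction of the mass, anything larger
  # signals a discretization failure.
  negmass <- sum(out[out < 0])
  if (negmass < -0.05 * sum(out[out > 0]))
    stop(sprintf("resolvent discretization failure: negative mass %.3g",
                 negmass))
  out[out < 0] <- 0
  cropped <- mass_precrop - sum(out)
  out <- out / sum(out)
  new_resolvent_kernel(out, params, n_theta, d,
                       mass_precrop = mass_precrop, cropped_mass = cropped)
}

#' Monte Carlo estimate of the direction-process resolvent
#'
#' Simulates `n_paths` Euler discretizations of the direction process with
#' Exp(alpha) lifetimes and histograms the endpoints on the same grid as
#' [fp_resolvent_numeric()].  Serves as the stochastic oracle for the
#' Fourier solution.  Deterministic given `seed`.
#'
#' @param params a [direction_process_params()] object (blur is not
#'   applied; the one-pixel endpoint binning plays its role).
#' @param n_paths number of sample paths.
#' @param dt Euler time step (px of travel).
#' @param seed optional RNG seed (`set.seed`).
#' @param d,n_theta output grid parameters.
#' @return a `resolvent_kernel` normalized by `n_paths`; its total mass is
#'   the fraction of endpoints inside the (2d+1)^2 window.
#' @export
mc_resolvent <- function(params, n_paths, dt = 0.1, seed = NULL, d, n_theta) {
  stopifnot(inherits(params, "direction_process_params"), n_paths >= 1)
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(seed)) set.seed(seed)
  res <- mc_resolvent_cpp(params$alpha, params$sigma, n_paths, dt,
                          as.integer(d), as.integer(n_theta))
  S <- 2L * d + 1L
  vals <- array(res$counts / n_paths, c(S, S, 2L * n_theta))
  new_resolvent_kernel(vals, params, n_theta, d,
                       mass_precrop = 1,
                       cropped_mass = 1 - res$inside / n_paths,
                       source = "monte-carlo")
}

#' Spatially smooth a binned kernel
#'
#' Applies a Gaussian blur of standard deviation `sigma` to every theta
#' layer (reflective boundary).  Histogram estimates (Monte Carlo or
#' statistical kernels, which integrate over one-pixel bins) become
#' directly comparable with [fp_resolvent_numeric()] output, which
#' carries the same bin integration plus the `blur_s` Gaussian.
#'
#' @param kernel a `cooc_kernel`, `resolvent_kernel` or
#'   `projective_kernel`.
#' @param sigma blur standard deviation in px.
#' @return kernel of the same class and mass.
#' @export
smooth_kernel <- function(kernel, sigma) {
  out <- kernel
  for (t in seq_len(dim(kernel)[3]))
    out[, , t] <- gaussian_blur(kernel[, , t], sigma)
  out
}

#' Relative l2 distance between two resolvent estimates (percent)
#'
#' Brings a Fourier solution (pixel-bin integrated plus its `blur_s`
#' Gaussian) and a Monte Carlo histogram (pixel-bin integrated only) to a
#' common spatial resolution before comparing: sub-pixel structure is not
#' representable in a one-pixel histogram, so both sides are smoothed to
#' an effective Gaussian scale of `resolution` px and the relative l2
#' difference of the renormalized kernels is returned.
#'
#' @param numeric a [fp_resolvent_numeric()] kernel.
#' @param mc a [mc_resolvent()] kernel on the same grid.
#' @param resolution common comparison scale (px), at least `blur_s`.
#' @return percentage `100 ||a - b||_2 / ||b||_2` (b = Fourier solution).
#' @export
resolvent_rel_l2 <- function(numeric, mc, resolution = 1) {
  stopifnot(identical(dim(numeric), dim(mc)))
  bs <- attr(numeric, "params")$blur_s
  if (resolution < bs) stop("resolution must be >= blur_s")
  a <- smooth_kernel(mc, resolution)
  b <- smooth_kernel(numeric, sqrt(resolution^2 - bs^2))
  av <- as.numeric(a) / sum(a); bv <- as.numeric(b) / sum(b)
  100 * sqrt(sum((av - bv)^2)) / sqrt(sum(bv^2))
}

#' Symmetrize a resolvent kernel to the projective line bundle
#'
#' Averages the four kernels `Gamma(g)`, `Gamma(g^-1)`, and their
#' pi-shifted counterparts.  Group inversion is evaluated through the
#' exact time-reversal identity of the direction process,
#' `Gamma(g^-1) = Gamma(-x, -y, theta)`, so all four terms are exact grid
#' operations: spatial point reflection and a half-turn shift of the theta
#' axis.  The output is exactly invariant under both maps and preserves
#' total mass.
#'
#' @param gamma a `resolvent_kernel` on `2 n_theta` theta samples (even
#'   count required so the pi-shift is an exact bin shift).
#' @return a `projective_kernel` of the same shape.
#' @export
symmetrize_projective <- function(gamma) {
  stopifnot(inherits(gamma, "resolvent_kernel"))
  v <- unclass(gamma)
  attributes(v) <- list(dim = dim(gamma))
  Nt <- dim(v)[3]
  if (Nt %% 2 != 0) stop("theta bin count must be even for the pi-shift")
  sg <- v[rev(seq_len(dim(v)[1])), rev(seq_len(dim(v)[2])), , drop = FALSE]
  shift <- c((Nt / 2 + 1):Nt, 1:(Nt / 2))
  # two-stage averaging keeps both invariances bit-exact (x + y == y + x)
  h <- (v + sg) / 2
  out <- (h + h[, , shift, drop = FALSE]) / 2
  structure(out, params = attr(gamma, "params"), d = attr(gamma, "d"),
            n_theta = attr(gamma, "n_theta"),
            theta_samples = attr(gamma, "theta_samples"),
            class = "projective_kernel")
}

#' @export
print.projective_kernel <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "projective (symmetrized) kernel: d=%d, 2*n_theta=%d, alpha=%g, D33=%g\n",
    attr(x, "d"), dim(x)[3], p$alpha, p$D33))
  invisible(x)
}

#' Fold a projective kernel onto the pi-periodic orientation grid
#'
#' Sums the theta samples at `theta` and `theta + pi` into the `n_theta`
#' orientation-difference layers of the co-occurrence grid, yielding a
#' `cooc_kernel` (kind "prob") directly comparable with statistical
#' kernels.  Mass is preserved.
#'
#' @param kernel a `projective_kernel` (or symmetric `resolvent_kernel`).
#' @return an unnormalized `cooc_kernel` of kind "prob".
#' @export
as_cooc_kernel <- function(kernel) {
  stopifnot(inherits(kernel, c("projective_kernel", "resolvent_kernel")))
  v <- unclass(kernel)
  attributes(v) <- list(dim = dim(kernel))
  Nt <- dim(v)[3]
  n_theta <- Nt %/% 2L
  out <- v[, , 1:n_theta, drop = FALSE] +
    v[, , (n_theta + 1):Nt, drop = FALSE]
  new_cooc_kernel(out, attr(kernel, "d"), n_theta, kind = "prob")
}

#' Spatial marginal of a lifted kernel
#'
#' Integrates (sums) the kernel over its orientation axis; mass is
#' preserved.  For the symmetrized projective kernel this produces the
#' double-sided "bow-tie" distribution.
#'
#' @param kernel a `cooc_kernel`, `resolvent_kernel` or
#'   `projective_kernel`.
#' @return nonnegative (2d+1) x (2d+1) matrix indexed [x, y].
#' @export
xy_marginal <- function(kernel) {
  v <- unclass(kernel)
  attributes(v) <- list(dim = dim(kernel))
  apply(v, c(1, 2), sum)
}

#' Logarithmic parameter grids for kernel fitting
#'
#' @param alpha_range,d33_range endpoints of the search ranges.
#' @param n_alpha,n_d33 number of grid values.
#' @return list with `alpha` and `d33` log-spaced vectors.
#' @export
fit_grids <- function(alpha_range = c(1e-5, 1e-2), n_alpha = 50,
                      d33_range = c(1e-6, 5e-3), n_d33 = 100) {
  list(alpha = exp(seq(log(alpha_range[1]), log(alpha_range[2]),
                       length.out = n_alpha)),
       d33 = exp(seq(log(d33_range[1]), log(d33_range[2]),
                     length.out = n_d33)))
}

#' Drop the identity bin of a co-occurrence grid
#'
#' Sets the (0, 0, 0) bin (zero offset, zero orientation difference) to
#' zero and renormalizes.  Pair statistics of distinct elements cannot
#' populate this bin, whereas the resolvent carries its short-travel
#' singularity there, so both sides of a statistics/model comparison drop
#' it.
#'
#' @param kernel a normalized or unnormalized `cooc_kernel`.
#' @return normalized `cooc_kernel` with an empty identity bin.
#' @export
drop_identity_bin <- function(kernel) {
  stopifnot(inherits(kernel, "cooc_kernel"))
  ctr <- attr(kernel, "d") + 1L
  kernel[ctr, ctr, 1L] <- 0
  kernel[] <- as.numeric(kernel) / sum(kernel)
  attr(kernel, "normalized") <- TRUE
  kernel
}

#' Fit direction-process parameters to a statistical kernel
#'
#' Grid search over (alpha, D33): for every pair the symmetrized,
#' pi-folded, normalized probabilistic kernel is built on the statistical
#' kernel's grid and compared by [kernel_distance()]; the least-squares
#' minimizer is returned.  Ties are broken toward smaller alpha, then
#' smaller D33.  By default the identity bin, which pair statistics of
#' distinct elements cannot contain but the resolvent's short-travel
#' singularity dominates, is excluded from both sides.
#'
#' @param k_stat a normalized `cooc_kernel`.
#' @param alpha_grid,d33_grid nonempty parameter grids.
#' @param blur_s spatial blur of the candidate kernels (px).
#' @param pad_factor periodic padding for the Fourier solve.
#' @param exclude_identity drop the (0,0,0) bin on both sides.
#' @param verbose print progress.
#' @return a `fit_result`: list (best_alpha, best_d33, error_percent,
#'   error_surface, alpha_grid, d33_grid).
#' @export
fit_kernel <- function(k_stat, alpha_grid, d33_grid, blur_s = 0.5,
                       pad_factor = 2, exclude_identity = TRUE,
                       verbose = FALSE) {
  stopifnot(inherits(k_stat, "cooc_kernel"))
  if (!length(alpha_grid) || !length(d33_grid)) stop("empty parameter grid")
  if (!isTRUE(attr(k_stat, "normalized")))
    stop("k_stat must be normalized")
  d <- attr(k_stat, "d"); n_theta <- attr(k_stat, "n_theta")
  if (exclude_identity) k_stat <- drop_identity_bin(k_stat)
  surf <- matrix(NA_real_, length(alpha_grid), length(d33_grid),
                 dimnames = list(signif(alpha_grid, 6), signif(d33_grid, 6)))
  for (ja in seq_along(alpha_grid)) {
    for (jd in seq_along(d33_grid)) {
      p <- direction_process_params(alpha_grid[ja], d33_grid[jd], blur_s)
      surf[ja, jd] <- tryCatch({
        gam <- fp_resolvent_numeric(p, d, n_theta, pad_factor)
        cand <- normalize_kernel(as_cooc_kernel(symmetrize_projective(gam)))
        if (exclude_identity) cand <- drop_identity_bin(cand)
        as.numeric(kernel_distance(k_stat, cand))
      }, error = function(e) Inf)   # degenerate corner of the grid
    }
    if (verbose)
      message(sprintf("alpha %g done (%d/%d)", alpha_grid[ja], ja,
                      length(alpha_grid)))
  }
  best <- min(surf)
  hits <- which(surf == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  structure(list(best_alpha = alpha_grid[hits[1, 1]],
                 best_d33 = d33_grid[hits[1, 2]],
                 error_percent = best,
                 error_surface = surf,
                 alpha_grid = alpha_grid, d33_grid = d33_grid),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("best fit: alpha=%.5g, D33=%.5g, error %.4f%%\n",
              x$best_alpha, x$best_d33, x$error_percent))
  invisible(x)
}
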