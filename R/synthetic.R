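# Synthetic inputs: direction-process sample paths (the generative model
# whose pair statistics the learned kernel must reproduce) and vessel-like
# phantoms with ground-truth group labels.

#' Sample direction-process paths as centerlines
#'
#' Simulates paths of the direction process (unit-speed motion, Brownian
#' orientation, Exp(alpha) lifetime), records the full trajectories
#' decimated to 1-px centerline pixels with the true tangent orientation
#' at each pixel, and rasterizes them onto a square canvas (all paths
#' start at the canvas center heading right).
#'
#' @param params a [direction_process_params()] object.
#' @param n_paths number of paths.
#' @param seed optional RNG seed.
#' @param canvas canvas side length in px; paths are clipped to it only in
#'   the rasterized mask (the returned path coordinates are unclipped).
#' @param dt Euler step.
#' @return a `direction_paths` object: list with `paths` (list of
#'   data.frames x, y, theta in origin-relative math coordinates),
#'   `centerlines` (canvas x canvas 0/1 matrix), `params`, `canvas`.
#' @export
sample_direction_paths <- function(params, n_paths, seed = NULL,
                                   canvas = 513, dt = 0.1) {
  stopifnot(inherits(params, "direction_process_params"), n_paths >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (canvas / 2 < 1 / params$alpha)
    warning(sprintf(
      "canvas %d px is small for mean path length %.0f px; paths clipped in the mask",
      canvas, 1 / params$alpha))
  raw <- sample_paths_cpp(params$alpha, params$sigma, as.integer(n_paths), dt)
  paths <- lapply(raw, function(m)
    data.frame(x = m[, 1], y = m[, 2], theta = m[, 3]))
  mask <- matrix(0L, canvas, canvas)
  ctr <- (canvas + 1) / 2
  for (p in paths) {
    px <- xy_to_px(p$x + ctr, p$y + ctr, canvas)
    ok <- px[, 1] >= 1 & px[, 1] <= canvas & px[, 2] >= 1 & px[, 2] <= canvas
    mask[px[ok, , drop = FALSE]] <- 1L
  }
  structure(list(paths = paths, centerlines = mask, params = params,
                 canvas = canvas, dt = dt),
            class = "direction_paths")
}

# Fold an angle to [-pi/2, pi/2) and snap to the nearest of n_theta bins.
orientation_bin_of <- function(theta, n_theta) {
  thf <- ((theta + pi / 2) %% pi) - pi / 2
  (as.integer(round_half_away((thf + pi / 2) / (pi / n_theta))) %% n_theta) + 1L
}

#' Learn a co-occurrence kernel from sampled paths
#'
#' Converts every path to an interest-point set using the true tangents
#' (snapped to `n_theta` bins) and accumulates shift-twist pair statistics
#' within each path.  Because pair gaps along an Exp(alpha) lifetime are
#' themselves exponentially distributed, the resulting statistics estimate
#' the (symmetrized) resolvent kernel with the same parameters.
#'
#' @param dp a [sample_direction_paths()] result.
#' @param d,n_theta kernel grid parameters.
#' @param normalize l1-normalize the result.
#' @param true_tangents use the exact tangent angles for the shift-twist
#'   rotation (the orientation difference is then binned once, matching
#'   the model kernel's single theta-bin integration); with `FALSE` the
#'   tangents are first snapped to the `n_theta` bins as an
#'   orientation-score pipeline would produce them.
#' @return a `cooc_kernel`.
#' @export
learn_kernel_from_paths <- function(dp, d, n_theta, normalize = TRUE,
                                    true_tangents = TRUE) {
  stopifnot(inherits(dp, "direction_paths"))
  sets <- lapply(dp$paths, function(p) {
    s <- data.frame(x = p$x, y = p$y,
                    k = orientation_bin_of(p$theta, n_theta))
    if (true_tangents) s$theta <- p$theta
    s
  })
  learn_cooc_kernel(sets, d, n_theta, normalize = normalize)
}

#' Parametric curves for phantom images
#'
#' Constructors for the curve types understood by [make_phantom()]:
#' straight segments, circle arcs and polynomial graphs `y(x)`.
#' Coordinates are math-frame pixels (x right, y up, origin at the
#' bottom-left pixel).  `gaps` is a list of arc-length intervals `c(a, b)`
#' (px) removed from the curve (interruptions).
#'
#' @param from,to segment endpoints (length-2 vectors).
#' @param center,radius,angles arc center, radius, and angular range
#'   (radians, counter-clockwise).
#' @param coefs polynomial coefficients (intercept first) of y(x).
#' @param x_range x interval over which the polynomial is drawn.
#' @param width stroke width in px.
#' @param intensity mean intensity of the curve (darker than background).
#' @param gaps list of arc-length intervals removed.
#' @return a `phantom_curve` list.
#' @name phantom_curves
NULL

#' @rdname phantom_curves
#' @export
curve_line <- function(from, to, width = 3, intensity = 0.3, gaps = list()) {
  structure(list(type = "line", from = from, to = to, width = width,
                 intensity = intensity, gaps = gaps),
            class = "phantom_curve")
}

#' @rdname phantom_curves
#' @export
curve_arc <- function(center, radius, angles, width = 3, intensity = 0.3,
                      gaps = list()) {
  structure(list(type = "arc", center = center, radius = radius,
                 angles = angles, width = width, intensity = intensity,
                 gaps = gaps), class = "phantom_curve")
}

#' @rdname phantom_curves
#' @export
curve_polynomial <- function(coefs, x_range, width = 3, intensity = 0.3,
                             gaps = list()) {
  structure(list(type = "polynomial", coefs = coefs, x_range = x_range,
                 width = width, intensity = intensity, gaps = gaps),
            class = "phantom_curve")
}

# Sample a curve at ~ds px spacing: data.frame (x, y, s, theta).
sample_curve <- function(curve, ds = 0.25) {
  if (curve$type == "line") {
    len <- sqrt(sum((curve$to - curve$from)^2))
    t <- seq(0, len, by = ds)
    dir <- (curve$to - curve$from) / len
    out <- data.frame(x = curve$from[1] + t * dir[1],
                      y = curve$from[2] + t * dir[2],
                      s = t, theta = atan2(dir[2], dir[1]))
  } else if (curve$type == "arc") {
    arc <- abs(diff(curve$angles)) * curve$radius
    t <- seq(0, arc, by = ds)
    sgn <- sign(diff(curve$angles))
    ang <- curve$angles[1] + sgn * t / curve$radius
    out <- data.frame(x = curve$center[1] + curve$radius * cos(ang),
                      y = curve$center[2] + curve$radius * sin(ang),
                      s = t, theta = ang + sgn * pi / 2)
  } else if (curve$type == "polynomial") {
    xs <- seq(curve$x_range[1], curve$x_range[2], by = ds / 2)
    ys <- outer(xs, seq_along(curve$coefs) - 1, `^`) %*% curve$coefs
    dx <- diff(xs); dy <- diff(ys)
    s <- c(0, cumsum(sqrt(dx^2 + dy^2)))
    out <- data.frame(x = xs, y = as.numeric(ys), s = s,
                      theta = atan2(c(dy, dy[length(dy)]),
                                    c(dx, dx[length(dx)])))
  } else stop("unknown curve type")
  out
}

drop_gaps <- function(samples, gaps) {
  keep <- rep(TRUE, nrow(samples))
  for (g in gaps) keep <- keep & !(samples$s >= g[1] & samples$s <= g[2])
  samples[keep, , drop = FALSE]
}

# Min distance from every pixel (math coords) to a sampled point set.
min_dist_raster <- function(size, sx, sy, chunk = 256L) {
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  px <- g$c; py <- size + 1 - g$r
  dmin <- rep(Inf, size * size)
  for (i0 in seq(1, length(sx), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(sx))
    m <- outer(px, sx[i0:i1], `-`)^2 + outer(py, sy[i0:i1], `-`)^2
    dmin <- pmin(dmin, do.call(pmin, as.data.frame(m)))
  }
  matrix(sqrt(dmin), size, size)
}

#' Phantom specification
#'
#' @param size canvas side in px.
#' @param curves list of [phantom_curves] (first-listed curve wins at
#'   overlap pixels).
#' @param noise_sigma additive Gaussian noise sd.
#' @param background background intensity.
#' @param seed RNG seed for the noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(size = 101, curves, noise_sigma = 0.02,
                         background = 0.85, seed = 1) {
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, TRUE,
                                            "phantom_curve")))
  sigs <- vapply(curves, function(cv) paste(deparse(cv), collapse = ""), "")
  if (anyDuplicated(sigs)) stop("identical curves in phantom spec")
  structure(list(size = as.integer(size), curves = curves,
                 noise_sigma = noise_sigma, background = background,
                 seed = seed), class = "phantom_spec")
}

#' Render a phantom sample
#'
#' Renders anti-aliased curves at their widths and intensities on a
#' uniform background, removes the gap intervals, adds Gaussian noise, and
#' returns the image together with the ground-truth segmentation,
#' 1-px centerlines, per-pixel group labels (curve index; overlap
#' pixels take the first-listed curve; 0 = background) and the overlap
#' mask (pixels covered by two or more curves).
#'
#' @param spec a [phantom_spec()].
#' @return a `synthetic_sample`: list (image, segmentation, centerlines,
#'   labels, spec).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  img <- matrix(spec$background, n, n)
  labels <- matrix(0L, n, n)
  centerlines <- matrix(0L, n, n)
  ncover <- matrix(0L, n, n)
  for (ci in rev(seq_along(spec$curves))) {
    cv <- spec$curves[[ci]]
    sm <- drop_gaps(sample_curve(cv), cv$gaps)
    if (!nrow(sm)) next
    dist <- min_dist_raster(n, sm$x, sm$y)
    cov <- clamp01(cv$width / 2 + 0.5 - dist)
    img <- img * (1 - cov) + cv$intensity * cov
    seg_c <- dist <= cv$width / 2
    labels[seg_c] <- ci
    ncover <- ncover + seg_c
    cl <- xy_to_px(round_half_away(sm$x), round_half_away(sm$y), n)
    ok <- cl[, 1] >= 1 & cl[, 1] <= n & cl[, 2] >= 1 & cl[, 2] <= n
    cli <- matrix(0L, n, n)
    cli[cl[ok, , drop = FALSE]] <- 1L
    centerlines[cli == 1L & seg_c] <- 1L
  }
  segmentation <- labels > 0L
  centerlines[!segmentation] <- 0L
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    img <- clamp01(img + matrix(stats::rnorm(n * n, 0, spec$noise_sigma),
                                n, n))
  }
  structure(list(image = img, segmentation = segmentation,
                 centerlines = centerlines, labels = labels,
                 overlap = ncover >= 2L, spec = spec),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("phantom %dx%d: %d curves, %d foreground px\n",
              nrow(x$image), ncol(x$image), length(x$spec$curves),
              sum(x$segmentation)))
  invisible(x)
}

# --- study phantoms -------------------------------------------------------
# 101 x 101 patches, 3 px vessels, background 0.85, two vessel shades
# (0.30 / 0.55, emulating the artery/vein contrast), noise sd 0.02.

#' Standard test phantoms
#'
#' Seeded 101x101 phantoms mirroring the structure classes around retinal
#' junctions: two crossing vessels, a bifurcation, parallel vessels, and a
#' single interrupted vessel (5 px gap).
#'
#' @param seed noise seed.
#' @return a `synthetic_sample`.
#' @name standard_phantoms
NULL

#' @rdname standard_phantoms
#' @export
phantom_crossing <- function(seed = 1) {
  make_phantom(phantom_spec(curves = list(
    curve_line(c(6, 26), c(96, 76), intensity = 0.30),
    curve_line(c(6, 76), c(96, 26), intensity = 0.55)), seed = seed))
}

#' @rdname standard_phantoms
#' @export
phantom_bifurcation <- function(seed = 1) {
  make_phantom(phantom_spec(curves = list(
    curve_line(c(6, 51), c(96, 51), intensity = 0.30),
    curve_line(c(51, 51), c(96, 86), intensity = 0.55)), seed = seed))
}

#' @rdname standard_phantoms
#' @export
phantom_parallel <- function(seed = 1) {
  make_phantom(phantom_spec(curves = list(
    curve_line(c(6, 40), c(96, 40), intensity = 0.30),
    curve_line(c(6, 62), c(96, 62), intensity = 0.55)), seed = seed))
}

#' @rdname standard_phantoms
#' @export
phantom_interrupted <- function(seed = 1) {
  make_phantom(phantom_spec(curves = list(
    curve_line(c(6, 36), c(96, 66), intensity = 0.40,
               gaps = list(c(45, 50)))), seed = seed))
}
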