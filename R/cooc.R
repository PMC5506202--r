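# Shift-twist invariant line co-occurrence statistics.
#
# The central object is the `cooc_kernel`: a (2d+1) x (2d+1) x n_theta
# nonnegative array indexed [dx, dy, dk] of relative positions (rotated
# into the reference point's frame, math y up) and relative pi-periodic
# orientations.  Layer j corresponds to the orientation difference
# (j-1) * pi / n_theta wrapped to [-pi/2, pi/2).

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

new_cooc_kernel <- function(values, d, n_theta, normalized = FALSE,
                            kind = "stat", dropped_weight = 0) {
  stopifnot(length(dim(values)) == 3,
            all(dim(values) == c(2 * d + 1, 2 * d + 1, n_theta)))
  structure(values, d = as.integer(d), n_theta = as.integer(n_theta),
            normalized = normalized, kind = kind,
            dropped_weight = dropped_weight, class = "cooc_kernel")
}

#' @export
print.cooc_kernel <- function(x, ...) {
  cat(sprintf(
    "line co-occurrence kernel (%s): d=%d, n_theta=%d, %s, mass %.6g\n",
    attr(x, "kind"), attr(x, "d"), attr(x, "n_theta"),
    if (isTRUE(attr(x, "normalized"))) "normalized" else "counts", sum(x)))
  invisible(x)
}

#' Morphological thinning to 1-pixel centerlines
#'
#' Zhang-Suen iterative thinning of a binary mask, producing an
#' 8-connected, one-pixel-wide skeleton that preserves the connectivity
#' of every foreground component.
#'
#' @param mask binary (0/1 or logical) matrix.
#' @return integer matrix of the same size with values in {0, 1}.
#' @export
thin_to_centerlines <- function(mask) {
  m <- as.matrix(mask)
  if (is.logical(m)) m <- m * 1L
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  shift <- function(p, dr, dc)
    p[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc, drop = FALSE]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      ctr <- pad[2:(nr + 1), 2:(nc + 1), drop = FALSE]
      # neighbours clockwise from north (raster up = row - 1)
      p2 <- shift(pad, -1L, 0L); p3 <- shift(pad, -1L, 1L)
      p4 <- shift(pad, 0L, 1L);  p5 <- shift(pad, 1L, 1L)
      p6 <- shift(pad, 1L, 0L);  p7 <- shift(pad, 1L, -1L)
      p8 <- shift(pad, 0L, -1L); p9 <- shift(pad, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
        (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
        (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- ctr == 1 & B >= 2 & B <= 6 & A == 1
      if (sub == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        ctr[cond] <- 0L
        pad[2:(nr + 1), 2:(nc + 1)] <- ctr
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- pad[2:(nr + 1), 2:(nc + 1), drop = FALSE]
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Interest points of a centerline mask
#'
#' One point per centerline pixel, carrying the dominant orientation bin
#' from an orientation map.  Coordinates are math-frame (x = col,
#' y = nrow + 1 - row, y up).
#'
#' @param centerlines binary matrix (1 = centerline pixel).
#' @param orientations an [dominant_orientations()] map defined on (at
#'   least) all centerline pixels.
#' @return `interest_points`: data.frame (x, y, k) with attribute
#'   `n_theta`.
#' @export
build_interest_points <- function(centerlines, orientations) {
  m <- as.matrix(centerlines)
  stopifnot(inherits(orientations, "orientation_map"))
  if (!identical(dim(m), dim(orientations$angle_index)))
    stop("shape mismatch between centerlines and orientations")
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    k <- orientations$angle_index[idx]
    if (anyNA(k)) {
      bad <- idx[which(is.na(k))[1], ]
      stop(sprintf(
        "centerline pixel (row %d, col %d) has no defined orientation",
        bad[1], bad[2]))
    }
  } else k <- integer(0)
  xy <- px_to_xy(idx[, 1], idx[, 2], nrow(m))
  pts <- data.frame(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]),
                    k = as.integer(k))
  structure(pts, n_theta = length(orientations$theta_bins),
            class = c("interest_points", "data.frame"))
}

#' Shift-twist differences of an interest-point set
#'
#' For every ordered pair within Chebyshev distance `d` the offset is
#' rotated by minus the reference point's bin angle and rounded to integer
#' pixel bins; the orientation difference is reduced mod pi.  Each ordered
#' pair contributes weight 1/2 at the rotated offset and 1/2 at its
#' antipode (centerlines carry no polarity).  Rotated offsets that round
#' outside the (2d+1)^2 grid are dropped; the lost weight is reported in
#' the `dropped_weight` attribute.
#'
#' @param points an [build_interest_points()] set (or data.frame with
#'   columns x, y, k and attribute n_theta).
#' @param d maximum pairing distance in pixels (Chebyshev).
#' @return `shift_twist_differences`: data.frame (dx, dy, dk, w) where dk
#'   is the 1-based orientation-difference layer, with attributes `d`,
#'   `n_theta`, `dropped_weight`.
#' @export
shift_twist_differences <- function(points, d) {
  if (d < 1) stop("d must be >= 1")
  n_theta <- attr(points, "n_theta")
  stopifnot(!is.null(n_theta))
  n <- nrow(points)
  if (n < 2) {
    out <- data.frame(dx = integer(0), dy = integer(0), dk = integer(0),
                      w = numeric(0))
    return(structure(out, d = as.integer(d), n_theta = n_theta,
                     dropped_weight = 0,
                     class = c("shift_twist_differences", "data.frame")))
  }
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  dx <- points$x[j] - points$x[i]
  dy <- points$y[j] - points$y[i]
  keep <- abs(dx) <= d & abs(dy) <= d
  i <- i[keep]; j <- j[keep]; dx <- dx[keep]; dy <- dy[keep]
  th <- theta_bins(n_theta)[points$k[i]]
  rx <- round_half_away(cos(th) * dx + sin(th) * dy)
  ry <- round_half_away(-sin(th) * dx + cos(th) * dy)
  dk <- ((points$k[j] - points$k[i]) %% n_theta) + 1L
  inside <- abs(rx) <= d & abs(ry) <= d
  dropped <- sum(!inside)  # both representatives lost together
  out <- data.frame(
    dx = c(rx[inside], -rx[inside]),
    dy = c(ry[inside], -ry[inside]),
    dk = c(dk[inside], dk[inside]),
    w = rep(0.5, 2 * sum(inside)))
  structure(out, d = as.integer(d), n_theta = n_theta,
            dropped_weight = dropped,
            class = c("shift_twist_differences", "data.frame"))
}

#' Accumulate shift-twist differences into a co-occurrence histogram
#'
#' @param differences a [shift_twist_differences()] set.
#' @param d,n_theta grid parameters; all differences must lie inside the
#'   (2d+1) x (2d+1) x n_theta grid.
#' @return an unnormalized `cooc_kernel` of counts.
#' @export
accumulate_kernel <- function(differences, d = attr(differences, "d"),
                              n_theta = attr(differences, "n_theta")) {
  S <- 2L * d + 1L
  if (nrow(differences) &&
      (any(abs(differences$dx) > d) || any(abs(differences$dy) > d) ||
       any(differences$dk < 1 | differences$dk > n_theta)))
    stop("difference outside kernel bounds")
  vals <- numeric(S * S * n_theta)
  if (nrow(differences)) {
    lin <- (differences$dx + d) + S * (differences$dy + d) +
      S * S * (differences$dk - 1L) + 1L
    acc <- rowsum(differences$w, lin)
    vals[as.integer(rownames(acc))] <- acc[, 1]
  }
  new_cooc_kernel(array(vals, c(S, S, n_theta)), d, n_theta,
                  dropped_weight = attr(differences, "dropped_weight") %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' l1-normalize a co-occurrence kernel
#'
#' @param kernel a `cooc_kernel` with positive total mass.
#' @return the kernel rescaled to sum to 1, `normalized` flag set.
#' @export
normalize_kernel <- function(kernel) {
  stopifnot(inherits(kernel, "cooc_kernel"))
  tot <- sum(kernel)
  if (tot <= 0) stop("kernel has zero mass; cannot normalize")
  out <- kernel
  out[] <- as.numeric(kernel) / tot
  attr(out, "normalized") <- TRUE
  out
}

#' Combine artery and vein co-occurrence histograms
#'
#' Arteries and veins are never directly connected, so their pair
#' statistics are accumulated separately and the unnormalized count
#' histograms are then added.
#'
#' @param arteries,veins unnormalized `cooc_kernel`s of identical shape.
#' @return their entrywise sum (unnormalized).
#' @export
combine_av_kernels <- function(arteries, veins) {
  stopifnot(inherits(arteries, "cooc_kernel"), inherits(veins, "cooc_kernel"))
  if (!identical(dim(arteries), dim(veins)))
    stop("kernel shapes differ")
  if (isTRUE(attr(arteries, "normalized")) ||
      isTRUE(attr(veins, "normalized")))
    stop("combine unnormalized count kernels, then normalize")
  out <- arteries
  out[] <- as.numeric(arteries) + as.numeric(veins)
  attr(out, "dropped_weight") <-
    (attr(arteries, "dropped_weight") %||% 0) +
    (attr(veins, "dropped_weight") %||% 0)
  out
}

#' Relative l2 distance between two normalized kernels (percent)
#'
#' `100 * ||k1 - k2||_2 / ||k1||_2`; with `symmetric = TRUE` the
#' denominator is `max(||k1||_2, ||k2||_2)`.  The raw (unnormalized) l2
#' difference is attached as attribute `l2`.
#'
#' @param k1,k2 normalized kernels of identical shape.
#' @param symmetric use the symmetric denominator.
#' @return nonnegative percentage.
#' @export
kernel_distance <- function(k1, k2, symmetric = FALSE) {
  if (!identical(dim(k1), dim(k2))) stop("kernel shapes differ")
  if (!isTRUE(attr(k1, "normalized")) || !isTRUE(attr(k2, "normalized")))
    stop("kernel_distance expects normalized kernels")
  l2 <- sqrt(sum((as.numeric(k1) - as.numeric(k2))^2))
  den <- if (symmetric)
    max(sqrt(sum(as.numeric(k1)^2)), sqrt(sum(as.numeric(k2)^2)))
  else sqrt(sum(as.numeric(k1)^2))
  structure(100 * l2 / den, l2 = l2)
}

#' Learn a co-occurrence kernel from centerline point sets
#'
#' Fast path of the full learning pipeline: accumulates shift-twist pair
#' histograms over one or more interest-point sets (pairs are never formed
#' across sets, e.g. across different images or different sampled paths)
#' and sums them.
#'
#' @param pointsets a single interest-point set or a list of them (each a
#'   data.frame with columns x, y, k).
#' @param d maximum pairing distance (Chebyshev, pixels).
#' @param n_theta number of orientation bins.
#' @param normalize l1-normalize the accumulated histogram.
#' @return a `cooc_kernel`.
#' @export
learn_cooc_kernel <- function(pointsets, d, n_theta, normalize = TRUE) {
  if (is.data.frame(pointsets)) pointsets <- list(pointsets)
  mats <- lapply(pointsets, function(p) {
    m <- cbind(as.numeric(p$x), as.numeric(p$y), as.numeric(p$k))
    if (!is.null(p$theta)) m <- cbind(m, as.numeric(p$theta))
    m
  })
  res <- cooc_accumulate_cpp(mats, as.integer(d), as.integer(n_theta))
  S <- 2L * d + 1L
  k <- new_cooc_kernel(array(res$counts, c(S, S, n_theta)), d, n_theta,
                       dropped_weight = res$dropped)
  if (normalize) normalize_kernel(k) else k
}
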