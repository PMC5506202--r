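# Perceptual grouping: connectivity x intensity affinities over lifted
# segmentation pixels, partitioned by self-tuning spectral clustering.

#' Luminosity/contrast normalization for retinal images
#'
#' Removes the luminosity drift as the best-fitting quadratic surface
#' (so any polynomial bias field up to second order is cancelled
#' exactly), divides by a large-scale Gaussian estimate of the local
#' standard deviation (contrast), and rescales affinely to [0, 1].
#'
#' @param image grayscale matrix.
#' @param background_scale Gaussian sigma (px) of the local-contrast
#'   estimate; should be much larger than the vessel width.
#' @return normalized image in [0, 1].
#' @export
normalize_retinal_intensity <- function(image, background_scale = 25) {
  image <- as.matrix(image)
  if (stats::sd(image) == 0) stop("constant image: zero local contrast")
  nr <- nrow(image); nc <- ncol(image)
  xs <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  X <- cbind(1, as.numeric(xs), as.numeric(ys), as.numeric(xs)^2,
             as.numeric(xs * ys), as.numeric(ys)^2)
  res <- matrix(stats::lm.fit(X, as.numeric(image))$residuals, nr, nc)
  sig <- sqrt(pmax(gaussian_blur(res^2, background_scale), 0))
  sig <- pmax(sig, 0.05 * max(sig))
  out <- res / sig
  (out - min(out)) / (max(out) - min(out))
}

#' Lift segmentation pixels to points with orientation and intensity
#'
#' @param orientations an orientation map defined on the segmentation.
#' @param segmentation logical matrix of vessel pixels.
#' @param intensity normalized intensity image.
#' @return data.frame (x, y, k, intensity) with attribute `n_theta`.
#' @export
lift_segmentation <- function(orientations, segmentation, intensity) {
  stopifnot(inherits(orientations, "orientation_map"))
  idx <- which(segmentation > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty segmentation")
  k <- orientations$angle_index[idx]
  if (anyNA(k)) stop("segmentation pixel with undefined orientation")
  xy <- px_to_xy(idx[, 1], idx[, 2], nrow(segmentation))
  structure(data.frame(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]),
                       k = as.integer(k),
                       intensity = intensity[idx],
                       row = idx[, 1], col = idx[, 2]),
            n_theta = length(orientations$theta_bins),
            class = c("lifted_points", "data.frame"))
}

#' Connectivity x intensity affinity matrix
#'
#' `A(i, j)` is the co-occurrence (or probabilistic) kernel evaluated at
#' the shift-twist difference of the two lifted points, symmetrized as the
#' mean of the i->j and j->i lookups, multiplied by a normalized Gaussian
#' in the intensity difference.  Pairs beyond the kernel's spatial support
#' get 0; the diagonal is 0.
#'
#' @param points a [lift_segmentation()] set (columns x, y, k, intensity).
#' @param kernel a normalized `cooc_kernel`.
#' @param sigma_int intensity bandwidth (on normalized intensities).
#' @return an m x m `affinity_matrix` (symmetric, nonnegative, zero
#'   diagonal) with attribute `sigma_int`.
#' @export
build_affinity <- function(points, kernel, sigma_int = 0.2) {
  if (sigma_int <= 0) stop("sigma_int must be positive")
  stopifnot(inherits(kernel, "cooc_kernel"))
  if (!isTRUE(attr(kernel, "normalized")))
    stop("kernel must be normalized")
  d <- attr(kernel, "d"); n_theta <- attr(kernel, "n_theta")
  S <- 2L * d + 1L
  m <- nrow(points)
  Dx <- -outer(points$x, points$x, `-`)   # [i, j] = x_j - x_i
  Dy <- -outer(points$y, points$y, `-`)
  th <- theta_bins(n_theta)[points$k]
  Ct <- matrix(cos(th), m, m); St <- matrix(sin(th), m, m)
  rx <- round_half_away(Ct * Dx + St * Dy)
  ry <- round_half_away(-St * Dx + Ct * Dy)
  dk <- (-outer(points$k, points$k, `-`)) %% n_theta    # (k_j - k_i) mod
  inside <- abs(rx) <= d & abs(ry) <= d
  kv <- matrix(0, m, m)
  lin <- (rx[inside] + d) + S * (ry[inside] + d) + S * S * dk[inside] + 1
  kv[inside] <- as.numeric(kernel)[lin]
  kv <- (kv + t(kv)) / 2
  G <- stats::dnorm(outer(points$intensity, points$intensity, `-`),
                    sd = sigma_int)
  A <- kv * G
  diag(A) <- 0
  structure(A, sigma_int = sigma_int, class = c("affinity_matrix", "matrix"))
}

# Product of Givens rotations over column pairs (i < j), fixed order.
givens_rotation <- function(angles, C) {
  R <- diag(C)
  a <- 1L
  for (i in seq_len(C - 1)) for (j in (i + 1):C) {
    cs <- cos(angles[a]); sn <- sin(angles[a])
    Rij <- R[, c(i, j)]
    R[, i] <- Rij[, 1] * cs + Rij[, 2] * sn
    R[, j] <- -Rij[, 1] * sn + Rij[, 2] * cs
    a <- a + 1L
  }
  R
}

# Alignment cost of Zelnik-Manor & Perona: sum_i ||Z_i||^2 / max_j Z_ij^2.
# Row norms are rotation invariant, so only the row maxima move.
rotation_cost <- function(X, angles, C, rown) {
  Z <- X %*% givens_rotation(angles, C)
  Z2 <- Z * Z
  mx <- Z2[cbind(seq_len(nrow(Z2)), max.col(Z2, ties.method = "first"))]
  # rows not represented in the candidate subspace get the worst ratio
  sum(ifelse(mx > 0, rown / mx, C))
}

align_eigenvectors <- function(X, max_iter = 100, step0 = 0.2) {
  C <- ncol(X)
  rown <- rowSums(X * X)
  K <- C * (C - 1) / 2
  ang <- numeric(K)
  cur <- rotation_cost(X, ang, C, rown)
  step <- step0
  h <- 1e-4
  for (it in seq_len(max_iter)) {
    g <- vapply(seq_len(K), function(a) {
      ap <- ang; ap[a] <- ap[a] + h
      am <- ang; am[a] <- am[a] - h
      (rotation_cost(X, ap, C, rown) - rotation_cost(X, am, C, rown)) / (2 * h)
    }, 0)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-10) break
    improved <- FALSE
    while (step > 1e-5) {
      cand <- ang - step * g / gn
      cc <- rotation_cost(X, cand, C, rown)
      if (cc < cur - 1e-12) {
        ang <- cand; cur <- cc; improved <- TRUE
        step <- min(step * 1.5, step0)
        break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  Z <- X %*% givens_rotation(ang, C)
  list(cost = cur, Z = Z,
       assign = max.col(Z * Z, ties.method = "first"))
}

#' Self-tuning spectral clustering
#'
#' Partitions a symmetric nonnegative affinity matrix.  The symmetrically
#' normalized affinity's leading eigenvectors are rotated (Givens
#' gradient descent) toward a maximally sparse indicator structure for
#' every candidate group count; the selected count is the largest
#' candidate whose alignment cost lies within a `tol` fraction of the
#' minimum.  Only candidates up to the number of positive eigenvalues are
#' considered (a structureless complete graph thus yields one group).
#' Rows with zero affinity to every other point are pre-assigned noise
#' (label -1).  Deterministic given `A`.
#'
#' @param A affinity matrix (symmetric, nonnegative).
#' @param max_groups largest candidate group count.
#' @param tol relative cost tolerance for the group-count selection.
#' @param max_iter gradient-descent iteration cap per candidate.
#' @return a `cluster_labels` object: list with `labels` (1..n_groups,
#'   -1 = noise), `n_groups`, `costs` (alignment cost per candidate).
#' @export
cluster_self_tuning <- function(A, max_groups = 10, tol = 0.01,
                                max_iter = 100) {
  A <- unclass(A)
  m <- nrow(A)
  stopifnot(m >= 2, max_groups >= 2, isTRUE(all.equal(A, t(A), tolerance = 1e-8)))
  deg <- rowSums(A)
  active <- deg > 0
  labels <- rep(-1L, m)
  ma <- sum(active)
  if (ma == 0) {
    return(structure(list(labels = labels, n_groups = 0L, costs = NA),
                     class = "cluster_labels"))
  }
  if (ma == 1) {
    labels[active] <- 1L
    return(structure(list(labels = labels, n_groups = 1L, costs = NA),
                     class = "cluster_labels"))
  }
  Aa <- A[active, active, drop = FALSE]
  ds <- 1 / sqrt(rowSums(Aa))
  L <- Aa * (ds %o% ds)
  eig <- eigen(L, symmetric = TRUE)
  Cmax <- min(max_groups, ma, sum(eig$values > 1e-10))
  Cmax <- max(Cmax, 1L)
  costs <- rep(NA_real_, Cmax)
  assigns <- vector("list", Cmax)
  costs[1] <- ma
  assigns[[1]] <- rep(1L, ma)
  if (Cmax >= 2) {
    for (C in 2:Cmax) {
      res <- align_eigenvectors(eig$vectors[, 1:C, drop = FALSE],
                                max_iter = max_iter)
      costs[C] <- res$cost
      assigns[[C]] <- res$assign
    }
  }
  ok <- which(costs <= (1 + tol) * min(costs) &
                vapply(assigns, function(a)
                  length(unique(a)), 0L) == seq_len(Cmax))
  Cbest <- if (length(ok)) max(ok) else which.min(costs)
  labels[active] <- assigns[[Cbest]]
  structure(list(labels = labels, n_groups = length(unique(assigns[[Cbest]])),
                 costs = costs),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("clustering: %d groups, sizes %s, %d noise points\n",
              x$n_groups,
              paste(table(x$labels[x$labels > 0]), collapse = ", "),
              sum(x$labels == -1L)))
  invisible(x)
}

#' Remove small groups as noise
#'
#' Groups with fewer than `min_size` members get label -1; the remaining
#' groups are relabeled contiguously (1..n).
#'
#' @param labels a `cluster_labels` object (or plain integer vector).
#' @param min_size minimum group size.
#' @return same type as the input.
#' @export
prune_small_groups <- function(labels, min_size) {
  stopifnot(min_size >= 1)
  lv <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  tab <- table(lv[lv > 0])
  keep <- as.integer(names(tab)[tab >= min_size])
  new <- rep(-1L, length(lv))
  for (i in seq_along(keep)) new[lv == keep[i]] <- i
  if (inherits(labels, "cluster_labels")) {
    structure(list(labels = new, n_groups = length(keep),
                   costs = labels$costs), class = "cluster_labels")
  } else new
}

#' End-to-end grouping of vessels in a segmented image
#'
#' Lifts the image with cake wavelets, takes dominant orientations on the
#' segmentation pixels (not necessarily centerlines), normalizes the
#' intensity, builds the connectivity x intensity affinity, clusters it
#' with [cluster_self_tuning()] and prunes small groups.
#'
#' @param image grayscale matrix in [0, 1] (vessels darker than
#'   background).
#' @param segmentation logical/0-1 matrix of vessel pixels.
#' @param kernel normalized `cooc_kernel` (statistical or probabilistic).
#' @param sigma_int intensity bandwidth.
#' @param wavelet_size cake-wavelet spatial size.
#' @param max_groups,min_size clustering controls; `min_size = NULL` uses
#'   `max(10, 1%)` of the point count.
#' @param background_scale intensity-normalization scale (px).
#' @return a `vessel_groups` object: list with `labels` (per lifted
#'   point), `label_map` (image-shaped; 0 = background or pruned),
#'   `n_groups`, `points`.
#' @export
group_vessels <- function(image, segmentation, kernel, sigma_int = 0.2,
                          wavelet_size = 31, max_groups = 10,
                          min_size = NULL, background_scale = 25) {
  segmentation <- as.matrix(segmentation) > 0
  if (!any(segmentation)) stop("empty segmentation")
  if (!identical(dim(as.matrix(image)), dim(segmentation)))
    stop("image and segmentation shapes differ")
  n_theta <- attr(kernel, "n_theta")
  wl <- make_cake_wavelets(n_theta, wavelet_size)
  sc <- orientation_score(image, wl)
  om <- dominant_orientations(sc, segmentation)
  In <- normalize_retinal_intensity(image, background_scale)
  pts <- lift_segmentation(om, segmentation, In)
  A <- build_affinity(pts, kernel, sigma_int)
  cl <- cluster_self_tuning(A, max_groups = max_groups)
  if (is.null(min_size)) min_size <- max(10, ceiling(0.01 * nrow(pts)))
  cl <- prune_small_groups(cl, min_size)
  lm <- matrix(0L, nrow(segmentation), ncol(segmentation))
  lm[cbind(pts$row, pts$col)] <- pmax(cl$labels, 0L)
  structure(list(labels = cl$labels, label_map = lm,
                 n_groups = cl$n_groups, points = pts, costs = cl$costs),
            class = "vessel_groups")
}

#' @export
print.vessel_groups <- function(x, ...) {
  cat(sprintf("vessel grouping: %d groups over %d lifted points\n",
              x$n_groups, length(x$labels)))
  invisible(x)
}

#' Best-matching label agreement with a ground truth
#'
#' Relabels predicted groups by the permutation maximizing agreement with
#' the ground truth (exhaustive over <= 6 groups) and returns the
#' fraction of points that agree.  Points with `truth == 0` (background)
#' or excluded flags are ignored.
#'
#' @param predicted,truth integer label vectors of equal length.
#' @param exclude logical vector of points to ignore.
#' @return agreement fraction in [0, 1].
#' @export
label_agreement <- function(predicted, truth, exclude = NULL) {
  keep <- truth > 0
  if (!is.null(exclude)) keep <- keep & !exclude
  p <- predicted[keep]; t <- truth[keep]
  pu <- sort(unique(p[p > 0])); tu <- sort(unique(t))
  if (!length(pu)) return(0)
  if (length(pu) > 6) stop("too many groups for exhaustive matching")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  # map each predicted group to a truth label (injective over min count)
  best <- 0
  tu_pad <- c(tu, rep(NA, max(0, length(pu) - length(tu))))
  for (pm in perms(tu_pad)) {
    map <- pm[seq_along(pu)]
    agree <- sum(vapply(seq_along(pu), function(i)
      if (is.na(map[i])) 0L else sum(p == pu[i] & t == map[i]), 0L))
    best <- max(best, agree)
  }
  best / length(t)
}
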