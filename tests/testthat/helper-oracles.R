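# Independent oracles used across the test files.

# O(N^2) plain-loop shift-twist accumulation, written independently of the
# package's vectorized/compiled path.  Points: data.frame x, y, k (1-based
# bin), optional theta (continuous radians).
brute_cooc <- function(points, d, n_theta) {
  S <- 2 * d + 1
  out <- array(0, c(S, S, n_theta))
  dropped <- 0
  n <- nrow(points)
  bins <- -pi / 2 + (seq_len(n_theta) - 1) * pi / n_theta
  rha <- function(x) sign(x) * floor(abs(x) + 0.5)
  for (i in seq_len(n)) {
    thi <- if (!is.null(points$theta)) points$theta[i] else bins[points$k[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- points$x[j] - points$x[i]
      dy <- points$y[j] - points$y[i]
      if (abs(dx) > d || abs(dy) > d) next
      rx <- rha(cos(thi) * dx + sin(thi) * dy)
      ry <- rha(-sin(thi) * dx + cos(thi) * dy)
      if (!is.null(points$theta)) {
        dd <- points$theta[j] - thi
        dd <- dd - pi * floor(dd / pi)
        dk <- rha(dd / (pi / n_theta)) %% n_theta
      } else {
        dk <- (points$k[j] - points$k[i]) %% n_theta
      }
      if (abs(rx) <= d && abs(ry) <= d) {
        out[rx + d + 1, ry + d + 1, dk + 1] <-
          out[rx + d + 1, ry + d + 1, dk + 1] + 0.5
        out[-rx + d + 1, -ry + d + 1, dk + 1] <-
          out[-rx + d + 1, -ry + d + 1, dk + 1] + 0.5
      } else dropped <- dropped + 1
    }
  }
  list(counts = out, dropped = dropped)
}

# Dark 1-px line through the image center at math angle phi on a bright
# background.
line_image <- function(n, phi, thickness = 0.6, bg = 1, fg = 0) {
  img <- matrix(bg, n, n)
  cc <- (n + 1) / 2
  for (r in 1:n) for (c in 1:n) {
    x <- c - cc; y <- (n + 1 - r) - cc
    if (abs(-sin(phi) * x + cos(phi) * y) < thickness) img[r, c] <- fg
  }
  img
}

# Localized elongated blob at math angle phi (analytic, no resampling).
oriented_blob <- function(n, phi, st = 2, sl = 15) {
  cc <- (n + 1) / 2
  g <- expand.grid(r = 1:n, c = 1:n)
  x <- g$c - cc; y <- cc - g$r
  u <- -sin(phi) * x + cos(phi) * y
  v <- cos(phi) * x + sin(phi) * y
  matrix(exp(-u^2 / (2 * st^2) - v^2 / (2 * sl^2)), n, n)
}

# Strip class/attributes, keep dims.
arr <- function(k) array(as.numeric(k), dim(k))

rel_l2 <- function(a, b) {
  a <- as.numeric(a) / sum(a); b <- as.numeric(b) / sum(b)
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}

# Connectivity kernel shared by grouping tests (built once per run).
grouping_kernel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- normalize_kernel(as_cooc_kernel(symmetrize_projective(
        fp_resolvent_numeric(direction_process_params(0.0024, 0.0017, 0.5),
                             65, 16))))
    }
    cache
  }
})
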