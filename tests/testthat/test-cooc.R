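test_that("thinning preserves empty masks and 1-px lines", {
  expect_equal(sum(thin_to_centerlines(matrix(0L, 10, 10))), 0)
  ln <- matrix(0L, 11, 11); ln[6, 2:10] <- 1L
  expect_equal(thin_to_centerlines(ln), ln)
  expect_error(thin_to_centerlines(matrix(2, 3, 3)), "binary")
})

test_that("a filled bar thins to a single 1-px connected path", {
  bar <- matrix(0L, 15, 31)
  bar[6:10, 3:29] <- 1L
  th <- thin_to_centerlines(bar)
  expect_true(all(th[bar == 0] == 0))
  # 1-px wide: each column of the bar interior has exactly one pixel
  cs <- colSums(th[, 7:25])                 # interior (ends erode a little)
  expect_true(all(cs >= 1 & cs <= 2))       # staircase corners allowed
  expect_gte(mean(cs == 1), 0.9)
  # connectivity preserved: flood fill from the first pixel reaches all
  pts <- which(th == 1, arr.ind = TRUE)
  visited <- rep(FALSE, nrow(pts))
  key <- paste(pts[, 1], pts[, 2])
  stack <- 1L; visited[1] <- TRUE
  while (length(stack)) {
    i <- stack[1]; stack <- stack[-1]
    nb <- which(abs(pts[, 1] - pts[i, 1]) <= 1 &
                  abs(pts[, 2] - pts[i, 2]) <= 1 & !visited)
    visited[nb] <- TRUE
    stack <- c(stack, nb)
  }
  expect_true(all(visited))
})

test_that("interest points carry the dominant orientation of each pixel", {
  img <- line_image(51, 0)
  wl <- make_cake_wavelets(8, 31)
  om <- dominant_orientations(orientation_score(img, wl),
                              matrix(TRUE, 51, 51))
  cl <- matrix(0L, 51, 51); cl[26, 10:40] <- 1L
  ip <- build_interest_points(cl, om)
  expect_equal(nrow(ip), 31)
  expect_true(all(ip$k == 5L))                 # theta = 0 bin
  expect_equal(attr(ip, "n_theta"), 8L)
  # empty centerline -> empty set
  expect_equal(nrow(build_interest_points(matrix(0L, 51, 51), om)), 0)
  # undefined orientation -> error naming the pixel
  om2 <- om; om2$angle_index[26, 12] <- NA
  om2$defined_mask[26, 12] <- FALSE
  expect_error(build_interest_points(cl, om2), "row 26, col 12")
})

test_that("collinear pairs accumulate on the axis; distant pairs are cut", {
  pts <- data.frame(x = c(0, 5), y = c(0, 0), k = c(5L, 5L))  # theta = 0
  attr(pts, "n_theta") <- 8L
  df <- shift_twist_differences(pts, d = 65)
  kk <- accumulate_kernel(df)
  expect_equal(sum(kk), 2)                     # two ordered pairs
  expect_equal(kk[5 + 66, 66, 1], 1)           # (+5, 0, 0): 2 x 1/2
  expect_equal(kk[-5 + 66, 66, 1], 1)
  far <- data.frame(x = c(0, 70), y = c(0, 0), k = c(1L, 1L))
  attr(far, "n_theta") <- 8L
  expect_equal(nrow(shift_twist_differences(far, d = 65)), 0)
  expect_error(shift_twist_differences(pts, d = 0), "d must be")
})

test_that("accumulation equals the O(N^2) brute-force oracle bin for bin", {
  set.seed(11)
  n <- 120
  pts <- data.frame(x = sample(-30:30, n, TRUE), y = sample(-30:30, n, TRUE),
                    k = sample(1:8, n, TRUE))
  attr(pts, "n_theta") <- 8L
  oracle <- brute_cooc(pts, d = 20, n_theta = 8)
  # compiled path
  kc <- learn_cooc_kernel(pts, d = 20, n_theta = 8, normalize = FALSE)
  expect_equal(unclass(kc)[seq_along(oracle$counts)],
               as.numeric(oracle$counts))
  expect_equal(attr(kc, "dropped_weight"), oracle$dropped)
  # vectorized R path
  kr <- accumulate_kernel(shift_twist_differences(pts, 20))
  expect_equal(as.numeric(kr), as.numeric(oracle$counts))
})

test_that("empty and single-difference histograms behave as defined", {
  pts <- data.frame(x = 1, y = 1, k = 1L); attr(pts, "n_theta") <- 4L
  expect_equal(sum(accumulate_kernel(shift_twist_differences(pts, 5))), 0)
  df <- data.frame(dx = 5L, dy = 0L, dk = 1L, w = 1)
  attr(df, "d") <- 6L; attr(df, "n_theta") <- 4L
  kk <- accumulate_kernel(df)
  expect_equal(sum(kk != 0), 1)
  expect_equal(kk[12, 7, 1], 1)
  bad <- df; bad$dx <- 9L
  expect_error(accumulate_kernel(bad), "bounds")
})

test_that("a straight line phantom concentrates all mass on its axis layer", {
  pts <- data.frame(x = 0:19, y = rep(0, 20), k = rep(5L, 20))
  attr(pts, "n_theta") <- 8L
  kk <- accumulate_kernel(shift_twist_differences(pts, 25))
  expect_equal(sum(kk[, , 1]), sum(kk))        # all in dk = 0 layer
  expect_equal(sum(kk[, 26, 1]), sum(kk))      # all on the dy = 0 row
})

test_that("normalization produces the probability simplex and is idempotent", {
  ones <- accumulate_kernel(
    structure(data.frame(dx = 0L, dy = 0L, dk = 1L, w = 1),
              d = 1L, n_theta = 2L))
  ones[] <- 1
  nk <- normalize_kernel(ones)
  expect_equal(as.numeric(nk), rep(1 / 18, 18))
  expect_equal(as.numeric(normalize_kernel(nk)), as.numeric(nk))
  set.seed(2)
  rnd <- ones; rnd[] <- runif(18)
  expect_equal(sum(normalize_kernel(rnd)), 1, tolerance = 1e-12)
  zero <- ones; zero[] <- 0
  expect_error(normalize_kernel(zero), "zero mass")
})

test_that("artery and vein histograms add; cross-label pairs are excluded", {
  set.seed(3)
  a <- data.frame(x = sample(0:20, 25, TRUE), y = sample(0:20, 25, TRUE),
                  k = sample(1:8, 25, TRUE))
  v <- data.frame(x = sample(30:50, 25, TRUE), y = sample(0:20, 25, TRUE),
                  k = sample(1:8, 25, TRUE))
  attr(a, "n_theta") <- attr(v, "n_theta") <- 8L
  ka <- learn_cooc_kernel(a, 60, 8, normalize = FALSE)
  kv <- learn_cooc_kernel(v, 60, 8, normalize = FALSE)
  comb <- combine_av_kernels(ka, kv)
  # zero vein histogram: combination is the artery histogram
  kz <- kv; kz[] <- 0
  expect_equal(as.numeric(combine_av_kernels(ka, kz)), as.numeric(ka))
  # identical histograms double
  expect_equal(as.numeric(combine_av_kernels(ka, ka)), 2 * as.numeric(ka))
  # label-separated accumulation = whole-set accumulation minus the
  # cross-label pair contributions (brute-force oracle)
  whole <- rbind(a, v); attr(whole, "n_theta") <- 8L
  kw <- brute_cooc(whole, 60, 8)
  cross <- kw$counts - brute_cooc(a, 60, 8)$counts -
    brute_cooc(v, 60, 8)$counts
  expect_equal(as.numeric(comb), as.numeric(kw$counts - cross))
  expect_error(combine_av_kernels(ka, learn_cooc_kernel(v, 10, 8,
                                                        normalize = FALSE)),
               "shapes")
})

test_that("kernel distance has its closed-form values", {
  pts <- data.frame(x = c(0, 3), y = c(0, 0), k = c(1L, 1L))
  attr(pts, "n_theta") <- 4L
  k1 <- learn_cooc_kernel(pts, 5, 4)
  expect_equal(as.numeric(kernel_distance(k1, k1)), 0)
  # two one-hot kernels at different bins: 100 * sqrt(2)
  a <- k1; a[] <- 0; a[1, 1, 1] <- 1; attr(a, "normalized") <- TRUE
  b <- k1; b[] <- 0; b[2, 1, 1] <- 1; attr(b, "normalized") <- TRUE
  expect_equal(as.numeric(kernel_distance(a, b)), 100 * sqrt(2))
  expect_equal(as.numeric(kernel_distance(a, b, symmetric = TRUE)),
               100 * sqrt(2))
  expect_error(kernel_distance(a, learn_cooc_kernel(pts, 4, 4)), "shapes")
})

test_that("the histogram is invariant under translation and bin rotation", {
  set.seed(7)
  n <- 150
  rr <- sqrt(runif(n)) * 20; aa <- runif(n, 0, 2 * pi)
  pts <- data.frame(x = rr * cos(aa), y = rr * sin(aa),
                    k = sample(1:8, n, TRUE))
  attr(pts, "n_theta") <- 8L
  k0 <- learn_cooc_kernel(pts, 38, 8, normalize = FALSE)
  # translation: exact invariance
  tr <- pts; tr$x <- tr$x + 7; tr$y <- tr$y - 12
  attr(tr, "n_theta") <- 8L
  kt <- learn_cooc_kernel(tr, 38, 8, normalize = FALSE)
  expect_equal(as.numeric(kt), as.numeric(k0))
  # rotation by one bin (pi/8): >= 99% of mass in identical bins
  phi <- pi / 8
  rt <- data.frame(x = cos(phi) * pts$x - sin(phi) * pts$y,
                   y = sin(phi) * pts$x + cos(phi) * pts$y,
                   k = (pts$k %% 8L) + 1L)
  attr(rt, "n_theta") <- 8L
  kr <- learn_cooc_kernel(rt, 38, 8, normalize = FALSE)
  same <- sum(pmin(as.numeric(kr), as.numeric(k0)))
  expect_gte(same / sum(k0), 0.99)
})

test_that("accumulated histograms are symmetric under the group inverse on bins", {
  # axis-aligned configuration: offsets and angles all bin-exact, so the
  # inverse-difference bin is exact
  pts <- data.frame(x = c(0, 4, 4), y = c(0, 0, 6), k = c(1L, 3L, 1L))
  attr(pts, "n_theta") <- 4L                   # bins at -90, -45, 0, 45
  kk <- accumulate_kernel(shift_twist_differences(pts, 10))
  v <- arr(kk)
  # sigma symmetry (antipode) is exact by construction
  expect_equal(v, v[21:1, 21:1, , drop = FALSE])
})
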