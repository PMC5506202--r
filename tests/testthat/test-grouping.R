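test_that("intensity normalization removes smooth bias fields", {
  ph <- phantom_crossing(seed = 2)
  img <- ph$image
  n <- nrow(img)
  bias <- 0.15 * outer(seq(-1, 1, length.out = n)^2,
                       seq(0, 1, length.out = n), `+`) / 2
  a <- normalize_retinal_intensity(img)
  b <- normalize_retinal_intensity(img + bias)
  expect_lt(sqrt(sum((a - b)^2)) / sqrt(sum(a^2)), 0.02)
  expect_error(normalize_retinal_intensity(matrix(1, 20, 20)), "constant")
})

test_that("normalized intensities keep the two vessel shades separated", {
  ph <- phantom_crossing(seed = 2)
  In <- normalize_retinal_intensity(ph$image)
  m1 <- mean(In[ph$labels == 1 & !ph$overlap])
  m2 <- mean(In[ph$labels == 2 & !ph$overlap])
  expect_gt(abs(m1 - m2), 0.2)
})

test_that("affinities follow the kernel lookup times the intensity Gaussian", {
  # small probabilistic kernel
  kp <- normalize_kernel(as_cooc_kernel(symmetrize_projective(
    fp_resolvent_numeric(direction_process_params(0.05, 0.002), 12, 8))))
  d <- attr(kp, "d")
  pts <- data.frame(x = c(10, 15), y = c(5, 5), k = c(5L, 5L),
                    intensity = c(0.4, 0.4))
  A <- build_affinity(pts, kp, sigma_int = 0.2)
  kbin <- (kp[5 + d + 1, d + 1, 1] + kp[-5 + d + 1, d + 1, 1]) / 2
  expect_equal(A[1, 2], kbin * stats::dnorm(0, sd = 0.2))
  expect_equal(A[1, 2], A[2, 1])
  expect_equal(diag(A), c(0, 0))
  # intensity gap of 3 sigma scales the affinity by exp(-9/2)
  pts2 <- pts; pts2$intensity <- c(0.4, 1.0)
  A2 <- build_affinity(pts2, kp, sigma_int = 0.2)
  expect_equal(A2[1, 2] / A[1, 2], exp(-9 / 2))
  # beyond the kernel support the affinity is zero
  pts3 <- pts; pts3$x <- c(0, 2 * d + 5)
  expect_equal(build_affinity(pts3, kp, 0.2)[1, 2], 0)
  expect_error(build_affinity(pts, kp, sigma_int = 0), "sigma_int")
  # widening sigma_int never decreases the relative weight of dissimilar
  # pairs
  r1 <- A2[1, 2] / A[1, 2]
  A3 <- build_affinity(pts, kp, 0.4); A4 <- build_affinity(pts2, kp, 0.4)
  expect_gte(A4[1, 2] / A3[1, 2], r1)
})

test_that("ideal block-diagonal affinities are partitioned exactly", {
  m <- 60
  A <- matrix(0, m, m)
  blocks <- rep(1:3, each = 20)
  for (g in 1:3) A[blocks == g, blocks == g] <- 1
  diag(A) <- 0
  cl <- cluster_self_tuning(A, max_groups = 6)
  expect_equal(cl$n_groups, 3L)
  expect_equal(length(unique(cl$labels[blocks == 1])), 1L)
  expect_equal(length(unique(cl$labels[blocks == 2])), 1L)
  expect_equal(length(unique(cl$labels[blocks == 3])), 1L)
  expect_equal(length(unique(paste(cl$labels, blocks))), 3L)
})

test_that("a structureless complete graph yields a single group", {
  m <- 40
  A <- matrix(1, m, m); diag(A) <- 0
  cl <- cluster_self_tuning(A, max_groups = 5)
  expect_equal(cl$n_groups, 1L)
  expect_true(all(cl$labels == 1L))
})

test_that("zero-affinity rows become noise and clustering is permutation invariant", {
  m <- 41
  A <- matrix(0, m, m)
  blocks <- c(rep(1:2, each = 20), 3)
  for (g in 1:2) A[blocks == g, blocks == g] <- 1
  diag(A) <- 0                                  # point 41 fully isolated
  cl <- cluster_self_tuning(A, max_groups = 5)
  expect_equal(cl$labels[41], -1L)
  expect_equal(cl$n_groups, 2L)
  set.seed(4)
  pm <- sample(m)
  cl2 <- cluster_self_tuning(A[pm, pm], max_groups = 5)
  # same partition after permutation
  expect_equal(cl2$labels == -1L, (cl$labels == -1L)[pm])
  agree <- label_agreement(cl2$labels, cl$labels[pm])
  expect_equal(agree, 1)
})

test_that("small groups are pruned and labels stay contiguous", {
  lab <- c(rep(1L, 120), rep(2L, 80), rep(3L, 3))
  pr <- prune_small_groups(lab, 10)
  expect_equal(sort(unique(pr)), c(-1L, 1L, 2L))
  expect_equal(sum(pr == -1L), 3)
  expect_equal(prune_small_groups(lab, 1), lab)
  allsmall <- prune_small_groups(c(1L, 2L), 5)
  expect_true(all(allsmall == -1L))
})

test_that("an interrupted curve is grouped across its gap end to end", {
  ph <- phantom_interrupted(seed = 5)
  vg <- group_vessels(ph$image, ph$segmentation, grouping_kernel())
  expect_equal(vg$n_groups, 1L)
  truth <- ph$labels[cbind(vg$points$row, vg$points$col)]
  expect_gte(label_agreement(vg$labels, truth), 0.99)
  # the single group spans both sides of the gap
  lm <- vg$label_map
  expect_gt(sum(lm[, 1:45] == 1), 0)
  expect_gt(sum(lm[, 56:101] == 1), 0)
  expect_error(group_vessels(ph$image, ph$segmentation * 0,
                             grouping_kernel()), "empty")
})
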