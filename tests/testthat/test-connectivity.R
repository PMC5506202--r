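test_that("the resolvent is a probability kernel on the padded domain", {
  rk <- fp_resolvent_numeric(direction_process_params(0.05, 0.002), 16, 8)
  expect_equal(attr(rk, "mass_precrop"), 1, tolerance = 1e-3)
  expect_true(all(rk >= 0))
  expect_equal(sum(rk), 1, tolerance = 1e-12)  # renormalized after crop
  expect_true(attr(rk, "cropped_mass") >= 0)
})

test_that("the deterministic limit decays exponentially along the ray", {
  p0 <- direction_process_params(0.05, 0, blur_s = 0)
  r0 <- fp_resolvent_numeric(p0, 32, 16)
  expect_equal(sum(r0[, , 17]), 1, tolerance = 1e-6)  # all mass at theta=0
  prof <- r0[33 + (1:30), 33, 17]
  ref <- exp(-0.05 * (1:30))
  expect_lt(max(abs(prof / prof[1] * ref[1] / ref - 1)), 0.02)
})

test_that("Monte Carlo paths with no angular noise stay on the ray", {
  mc <- mc_resolvent(direction_process_params(0.1, 0), 2000, dt = 0.1,
                     seed = 5, d = 16, n_theta = 8)
  v <- arr(mc)
  expect_equal(sum(v[, 17, 9]), sum(v))        # y = 0, theta = 0 only
  expect_equal(sum(v[1:16, , ]), 0)            # no mass at x < 0
})

test_that("large decay rates keep endpoints near the origin", {
  mc <- mc_resolvent(direction_process_params(20, 0.01), 5000, dt = 0.01,
                     seed = 5, d = 16, n_theta = 8)
  v <- arr(mc)
  near <- sum(v[17 + (-1:1), 17 + (-1:1), ])
  expect_gte(near / sum(v), 0.99)
})

test_that("Monte Carlo estimates are deterministic given the seed", {
  p <- direction_process_params(0.05, 0.003)
  m1 <- mc_resolvent(p, 3000, dt = 0.1, seed = 99, d = 12, n_theta = 8)
  m2 <- mc_resolvent(p, 3000, dt = 0.1, seed = 99, d = 12, n_theta = 8)
  expect_identical(as.numeric(m1), as.numeric(m2))
  expect_error(mc_resolvent(p, 10, dt = 0, d = 5, n_theta = 4), "dt")
})

test_that("symmetrization fixes its invariances exactly and preserves mass", {
  rk <- fp_resolvent_numeric(direction_process_params(0.05, 0.002), 16, 8)
  ps <- symmetrize_projective(rk)
  expect_equal(sum(ps), sum(rk), tolerance = 1e-12)
  v <- arr(ps)
  S <- dim(v)[1]; Nt <- dim(v)[3]
  expect_equal(v, v[S:1, S:1, , drop = FALSE])                 # inversion
  expect_equal(v, v[, , c((Nt / 2 + 1):Nt, 1:(Nt / 2)), drop = FALSE])
  # applying the symmetrization to an already symmetric kernel is a fixed
  # point
  ps2 <- symmetrize_projective(
    structure(ps, class = "resolvent_kernel", d = attr(ps, "d"),
              n_theta = attr(ps, "n_theta"), params = attr(ps, "params"),
              theta_samples = attr(ps, "theta_samples")))
  expect_equal(as.numeric(ps2), as.numeric(ps), tolerance = 1e-14)
})

test_that("the symmetrized kernel equals its group inverse on exact bins", {
  rk <- fp_resolvent_numeric(direction_process_params(0.05, 0.002), 16, 8)
  ps <- symmetrize_projective(rk)
  v <- arr(ps)
  ts <- attr(rk, "theta_samples")
  ip <- which(abs(ts - pi / 2) < 1e-9)
  im <- which(abs(ts + pi / 2) < 1e-9)
  # g = (x, y, pi/2) has g^{-1} = (-y, x, -pi/2), an exact grid map
  err <- 0
  for (ix in 1:33) for (iy in 1:33) {
    x <- ix - 17; y <- iy - 17
    err <- max(err, abs(v[ix, iy, ip] - v[-y + 17, x + 17, im]))
  }
  expect_lt(err / max(v), 1e-4)
})

test_that("odd theta sample counts cannot be pi-shifted", {
  rk <- fp_resolvent_numeric(direction_process_params(0.05, 0.002), 8, 4)
  bad <- rk[, , 1:7]
  attributes(bad) <- c(attributes(bad), attributes(rk)[c("params", "d")])
  class(bad) <- "resolvent_kernel"
  expect_error(symmetrize_projective(bad), "even")
})

test_that("spatial marginals preserve mass and double-sidedness", {
  rk <- fp_resolvent_numeric(direction_process_params(0.05, 0.002), 16, 8)
  ps <- symmetrize_projective(rk)
  m <- xy_marginal(ps)
  expect_equal(sum(m), sum(ps), tolerance = 1e-12)
  # bow-tie: both forward and backward lobes carry mass
  expect_gt(sum(m[18:33, ]), 0.2 * sum(m))
  expect_gt(sum(m[1:16, ]), 0.2 * sum(m))
  # one-hot kernel -> one-hot marginal
  oh <- rk; oh[] <- 0; oh[3, 5, 2] <- 1
  expect_equal(which(xy_marginal(oh) == 1), 3L + 33L * 4L)
})

test_that("fitting a kernel to itself recovers its parameters with zero error", {
  a0 <- 0.03; d0 <- 0.002
  gam <- fp_resolvent_numeric(direction_process_params(a0, d0, 0.5), 12, 8)
  kstat <- normalize_kernel(as_cooc_kernel(symmetrize_projective(gam)))
  fit <- fit_kernel(kstat, alpha_grid = c(0.01, a0, 0.09),
                    d33_grid = c(5e-4, d0, 8e-3))
  expect_equal(fit$best_alpha, a0)
  expect_equal(fit$best_d33, d0)
  expect_equal(fit$error_percent, 0, tolerance = 1e-8)
  expect_equal(dim(fit$error_surface), c(3L, 3L))
  expect_error(fit_kernel(kstat, numeric(0), c(1e-3)), "empty")
})

test_that("comparing numeric and Monte Carlo resolvents needs a common scale", {
  p <- direction_process_params(0.1, 0.002)
  fp <- fp_resolvent_numeric(p, 12, 8, pad_factor = 4)
  mc <- mc_resolvent(p, 1e5, dt = 0.1, seed = 2, d = 12, n_theta = 8)
  expect_error(resolvent_rel_l2(fp, mc, resolution = 0.1), "blur_s")
  expect_lt(resolvent_rel_l2(fp, mc), 10)
})
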