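test_that("path sampling is deterministic and respects the zero-diffusion limit", {
  p <- direction_process_params(0.05, 0.001)
  d1 <- sample_direction_paths(p, 20, seed = 9, canvas = 101)
  d2 <- sample_direction_paths(p, 20, seed = 9, canvas = 101)
  expect_identical(d1$paths, d2$paths)
  expect_identical(d1$centerlines, d2$centerlines)
  # D33 = 0: straight horizontal centerlines
  d0 <- sample_direction_paths(direction_process_params(0.05, 0), 10,
                               seed = 1, canvas = 101)
  for (pp in d0$paths) {
    expect_true(all(pp$y == 0))
    expect_true(all(diff(pp$x) == 1))
  }
  expect_warning(sample_direction_paths(direction_process_params(0.005, 0.001),
                                        2, seed = 1, canvas = 51), "small")
})

test_that("phantom labels partition the foreground and gaps interrupt it", {
  ph <- make_phantom(phantom_spec(curves = list(
    curve_line(c(6, 36), c(96, 66), intensity = 0.4,
               gaps = list(c(45, 50)))), noise_sigma = 0, seed = 1))
  expect_true(all((ph$labels > 0) == ph$segmentation))
  expect_true(all(ph$centerlines[!ph$segmentation] == 0))
  # gap: two connected components in the segmentation, one label id
  comp <- function(mask) {
    pts <- which(mask, arr.ind = TRUE)
    n <- nrow(pts); lab <- integer(n); cur <- 0L
    for (s in seq_len(n)) {
      if (lab[s]) next
      cur <- cur + 1L; lab[s] <- cur; stack <- s
      while (length(stack)) {
        i <- stack[1]; stack <- stack[-1]
        nb <- which(abs(pts[, 1] - pts[i, 1]) <= 1 &
                      abs(pts[, 2] - pts[i, 2]) <= 1 & lab == 0L)
        lab[nb] <- cur; stack <- c(stack, nb)
      }
    }
    cur
  }
  expect_equal(comp(ph$segmentation), 2L)
  expect_equal(length(unique(ph$labels[ph$segmentation])), 1L)
})

test_that("a noiseless single line renders as a clean band with one label", {
  ph <- make_phantom(phantom_spec(curves = list(
    curve_line(c(11, 51), c(91, 51), width = 3, intensity = 0.3)),
    noise_sigma = 0, seed = 1))
  expect_equal(sort(unique(as.integer(ph$labels))), c(0L, 1L))
  expect_equal(sum(ph$segmentation[49:53, 30]), 3)  # 3 px band
  expect_equal(ph$image[51, 30], 0.3)
  expect_equal(ph$image[5, 5], ph$spec$background)
})

test_that("crossing overlap pixels take the first-listed curve", {
  ph <- make_phantom(phantom_spec(curves = list(
    curve_line(c(6, 51), c(96, 51), intensity = 0.3),
    curve_line(c(51, 6), c(51, 96), intensity = 0.6)),
    noise_sigma = 0, seed = 1))
  expect_equal(sort(unique(as.integer(ph$labels))), 0:2)
  expect_true(all(ph$labels[ph$overlap] == 1L))
  expect_equal(ph$image[51, 51], 0.3)
  expect_error(make_phantom(phantom_spec(curves = list(
    curve_line(c(0, 0), c(9, 9)), curve_line(c(0, 0), c(9, 9))))),
    "identical")
})

test_that("phantom rendering is reproducible for a fixed seed", {
  a <- phantom_crossing(seed = 11)
  b <- phantom_crossing(seed = 11)
  expect_identical(a$image, b$image)
  expect_false(identical(a$image, phantom_crossing(seed = 12)$image))
})

test_that("arc and polynomial curves carry consistent tangents", {
  arc <- sample_curve(curve_arc(c(50, 50), 30, c(0, pi / 2)))
  # tangent perpendicular to the radius everywhere
  rad <- atan2(arc$y - 50, arc$x - 50)
  expect_lt(max(abs(((arc$theta - rad - pi / 2 + pi) %% (2 * pi)) - pi)),
            1e-6)
  pol <- sample_curve(curve_polynomial(c(10, 0.5, 0.01), c(0, 40)))
  slope <- 0.5 + 0.02 * pol$x
  expect_lt(max(abs(tan(pol$theta) - slope)), 0.05)
})
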