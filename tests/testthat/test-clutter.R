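make_matrix <- function(samples) radar_matrix(samples, slow_period_s = 0.05)

test_that("clutter recursion limiting behaviours hold exactly", {
  set.seed(1)
  x <- make_matrix(matrix(rnorm(200), 40, 5))
  # alpha = 1: clutter frozen at the first frame
  cs1 <- suppress_clutter(x, alpha = 1, init = "first-frame")
  for (t in seq_len(40)) {
    expect_equal(cs1$clutter$samples[t, ], x$samples[1, ], tolerance = 1e-12)
  }
  # alpha = 0: clutter tracks the raw echo, residual identically zero
  cs0 <- suppress_clutter(x, alpha = 0)
  expect_equal(cs0$clutter$samples, x$samples, tolerance = 1e-12)
  expect_true(all(abs(cs0$residual$samples) < 1e-12))
})

test_that("a constant scene leaves zero residual for any alpha", {
  x <- make_matrix(matrix(rep(c(2, 5, -1), each = 30), 30, 3))
  for (a in c(0, 0.3, 0.9, 1)) {
    cs <- suppress_clutter(x, alpha = a, init = "first-frame")
    expect_true(all(abs(cs$residual$samples) < 1e-12))
  }
})

test_that("the step response decays geometrically as the hand-unrolled recursion", {
  # unit step at frame 5 in one bin, alpha = 0.9, first-frame init
  s <- matrix(0, 20, 1)
  s[5:20, 1] <- 1
  cs <- suppress_clutter(make_matrix(s), alpha = 0.9, init = "first-frame")
  for (t in 5:20) {
    expect_equal(cs$clutter$samples[t, 1], 1 - 0.9^(t - 4), tolerance = 1e-12)
    expect_equal(cs$residual$samples[t, 1], 0.9^(t - 4), tolerance = 1e-12)
  }
})

test_that("the clutter recursion is linear under zero initialization", {
  set.seed(7)
  x1 <- matrix(rnorm(150), 30, 5)
  x2 <- matrix(rnorm(150), 30, 5)
  r1 <- suppress_clutter(make_matrix(x1), alpha = 0.8, init = "zeros")
  r2 <- suppress_clutter(make_matrix(x2), alpha = 0.8, init = "zeros")
  r12 <- suppress_clutter(make_matrix(x1 + x2), alpha = 0.8, init = "zeros")
  expect_equal(r12$residual$samples,
               r1$residual$samples + r2$residual$samples, tolerance = 1e-10)
})

test_that("variance localization finds the subject and preserves the peak width", {
  sc <- scene_config(duration_s = 30, subject_bin = 10, noise_sigma = 0)
  scene <- simulate_scene(sc)
  cs <- suppress_clutter(scene$matrix)
  vp <- variance_localize(cs$residual)
  expect_false(vp$degenerate)
  expect_equal(vp$selected_bin, 10L)
  expect_true(vp$preserved_width[1] <= 10 && vp$preserved_width[2] >= 10)
})

test_that("variance agrees with the brute-force oracle and larger amplitude wins", {
  tt <- (0:399) / 20
  s <- matrix(0, 400, 12)
  s[, 3] <- 1.0 * sin(2 * pi * 0.3 * tt)
  s[, 7] <- 2.0 * sin(2 * pi * 0.2 * tt)
  vp <- variance_localize(make_matrix(s))
  expect_equal(vp$selected_bin, 7L)
  expect_equal(vp$variance, brute_variance_profile(s), tolerance = 1e-12)
})

test_that("a perfectly static scene is flagged degenerate", {
  vp <- variance_localize(make_matrix(matrix(4, 50, 6)))
  expect_true(vp$degenerate)
  expect_true(is.na(vp$selected_bin))
})

test_that("argmax ties break to the lowest bin index", {
  tt <- (0:199) / 20
  s <- matrix(0, 200, 5)
  s[, 2] <- sin(2 * pi * 0.25 * tt)
  s[, 4] <- sin(2 * pi * 0.25 * tt)
  vp <- variance_localize(make_matrix(s))
  expect_equal(vp$selected_bin, 2L)
})
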