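test_that("r_squared reproduces the hand-computed example and its identities", {
  # 1 - (0.01 + 0.01 + 0.04 + 0.04) / 5 = 0.98
  expect_equal(r_squared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8)), 0.98,
               tolerance = 1e-12)
  a <- c(2, 4, 1, 7)
  expect_identical(r_squared(a, a), 1)
  expect_equal(r_squared(a, rep(mean(a), 4)), 0)
  # worse than the mean is legal and negative
  expect_lt(r_squared(c(1, 2, 3), c(3, 1, 5)), 0)
  expect_error(r_squared(1:3, 1:4), class = "sbdar_validation")
})

test_that("two normalizations of R^2 agree to machine precision", {
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(50)
    f <- a + rnorm(50, sd = 0.3)
    n <- length(a)
    alt <- 1 - (sum((a - f)^2) / n) / (sum((a - mean(a))^2) / n)
    expect_equal(r_squared(a, f), alt, tolerance = 1e-12)
  }
})

test_that("a pure sine window is recovered with its parameters and R^2 ~ 1", {
  tt <- seq(0, 30, by = 0.05)
  fit <- fit_sine_series(2 * sin(2 * pi * 0.25 * tt + 1.0), tt)
  expect_gte(fit$r_squared, 0.999)
  expect_equal(fit$amplitude, 2, tolerance = 1e-3)
  expect_equal(fit$omega, 2 * pi * 0.25, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_true(all(fit$amplitude >= 0))
})

test_that("a constant window scores R^2 = 0 by convention", {
  tt <- (0:599) / 20
  fit <- fit_sine_series(rep(3, 600), tt)
  expect_equal(fit$r_squared, 0)
})

test_that("white-noise windows fall below the gate in at least 95% of cases", {
  set.seed(99)
  tt <- (0:599) / 20
  r2 <- vapply(1:100, function(i) {
    fit_sine_series(rnorm(600), tt)$r_squared
  }, numeric(1))
  expect_gte(mean(r2 < 0.5), 0.95)
})

test_that("gating tiles windows, keeps pure sines, and honours a zero threshold", {
  tt <- (0:2399) / 20
  sig <- sin(2 * pi * 0.25 * tt)
  gm <- gate_windows(sig, fs = 20, window_s = 30)
  expect_equal(nrow(gm$windows), 4)
  expect_true(all(gm$windows$keep))
  gm0 <- gate_windows(rnorm(1200), fs = 20, window_s = 30, r2_threshold = 0)
  expect_true(all(gm0$windows$keep))
  expect_error(gate_windows(sig[1:100], fs = 20, window_s = 30),
               class = "sbdar_validation")
})

test_that("raising the gate threshold never increases the number of kept windows", {
  set.seed(12)
  tt <- (0:2999) / 20
  sig <- sin(2 * pi * 0.3 * tt) * rep(c(1, 0.2, 1, 0.05, 1), each = 600) +
    rnorm(3000, sd = 0.4)
  kept <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(thr) {
    sum(gate_windows(sig, 20, r2_threshold = thr)$windows$keep)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("a movement epoch covering one window is rejected and matches ground truth", {
  sc <- demo_scene(bpm = 15, seed = 22, duration_s = 150,
                   movement_epochs = list(c(60, 90, 3)))
  scene <- simulate_scene(sc)
  cs <- suppress_clutter(scene$matrix)
  vp <- variance_localize(cs$residual)
  series <- dwt_denoise(rowMeans(
    cs$residual$samples[, vp$preserved_width[1]:vp$preserved_width[2],
                        drop = FALSE]))
  gm <- gate_windows(series, 20)
  expect_false(gm$windows$keep[3])
  expect_true(all(gm$windows$keep[c(1, 2, 4, 5)]))
  expect_equal(gate_agreement(gm$windows, scene$truth), 1)
})

test_that("gate decisions agree with ground truth across seeded scenes", {
  agreements <- vapply(1:10, function(s) {
    scene <- simulate_scene(demo_scene(bpm = 10 + s, seed = 100 + s,
                                       duration_s = 300,
                                       movement_epochs = list(
                                         c(60, 90, 3), c(210, 240, 3))))
    cs <- suppress_clutter(scene$matrix)
    vp <- variance_localize(cs$residual)
    series <- dwt_denoise(rowMeans(
      cs$residual$samples[, vp$preserved_width[1]:vp$preserved_width[2],
                          drop = FALSE]))
    gate_agreement(gate_windows(series, 20)$windows, scene$truth)
  }, numeric(1))
  expect_gte(mean(agreements), 0.9)
})
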