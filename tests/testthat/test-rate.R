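test_that("FFT peak picking reads pure and mixed tones correctly", {
  tt <- (0:1199) / 20
  expect_equal(estimate_rate_fft(sin(2 * pi * 0.25 * tt), 20)$rate_bpm, 15,
               tolerance = 1e-4)
  # larger in-band line wins
  two <- 1.0 * sin(2 * pi * 0.30 * tt) + 0.4 * sin(2 * pi * 0.15 * tt)
  expect_equal(estimate_rate_fft(two, 20)$rate_bpm, 18, tolerance = 0.3)
  # out-of-band peak ignored
  mix <- 0.5 * sin(2 * pi * 0.20 * tt) + 2.0 * sin(2 * pi * 1.5 * tt)
  expect_equal(estimate_rate_fft(mix, 20)$rate_bpm, 12, tolerance = 0.3)
})

test_that("estimates respect the invariants and the duration guard", {
  tt <- (0:1199) / 20
  est <- estimate_rate_fft(sin(2 * pi * 0.31 * tt), 20)
  expect_equal(est$rate_bpm, 60 * est$peak_freq_hz)
  expect_gte(est$peak_freq_hz, est$search_band_hz[1] - 0.005)
  expect_lte(est$peak_freq_hz, est$search_band_hz[2] + 0.005)
  expect_error(estimate_rate_fft(sin(tt[1:100]), 20), "minimum",
               class = "sbdar_validation")
  expect_error(estimate_rate_fft(sin(2 * pi * tt), 20,
                                 search_band_hz = c(0.2, 15)),
               class = "sbdar_validation")
})

test_that("a noiseless sinusoid is located within one FFT bin across the band", {
  for (f0 in c(0.17, 0.253, 0.42, 0.61)) {
    tt <- (0:1999) / 20
    est <- estimate_rate_fft(sin(2 * pi * f0 * tt), 20)
    expect_lt(abs(est$peak_freq_hz - f0), 0.005)
  }
})

test_that("the gapped spectrum preserves phase across removed segments", {
  tt_full <- (0:5999) / 20
  x <- sin(2 * pi * 0.26 * tt_full)
  keep <- c(1:1200, 1801:3600, 4201:6000)
  est <- estimate_rate_fft(x[keep], 20, times = tt_full[keep])
  expect_lt(abs(est$peak_freq_hz - 0.26), 0.003)
})

test_that("both baselines read a clean simulated scene exactly", {
  scene <- simulate_scene(scene_config(duration_s = 60,
                                       breathing_rate_bpm = 15,
                                       subject_bin = 12, noise_sigma = 0))
  ac <- baseline_autocorr_fft(scene$matrix)
  ms <- baseline_meansub_fft(scene$matrix)
  expect_equal(ac$rate_bpm, 15, tolerance = 0.3)
  expect_equal(ms$rate_bpm, 15, tolerance = 0.3)
  expect_equal(attr(ac, "selected_bin"), 12L)
  expect_equal(attr(ms, "selected_bin"), 12L)
  expect_gt(attr(ac, "selected_lag"), 0L)
})

test_that("degenerate static scenes raise the degenerate condition", {
  m <- radar_matrix(matrix(5, 1200, 8), slow_period_s = 0.05)
  expect_error(baseline_autocorr_fft(m), class = "sbdar_degenerate")
  expect_error(baseline_meansub_fft(m), class = "sbdar_degenerate")
})

test_that("the recursive filter tracks drifting clutter better than mean subtraction", {
  # linear clutter drift: mean subtraction leaves the full trend, the
  # recursive background absorbs it; compare out-of-band (sub-band)
  # residual energy fractions
  tt <- (0:2399) / 20
  drift <- 0.5 * tt / max(tt)
  x <- matrix(drift + c(sin(2 * pi * 0.25 * tt)), ncol = 1)
  m <- radar_matrix(x, slow_period_s = 0.05)
  rec <- suppress_clutter(m, alpha = 0.97)$residual$samples[, 1]
  msr <- x[, 1] - mean(x[, 1])
  oob <- function(s) {
    p <- Mod(fft(s - mean(s)))^2
    fr <- (seq_along(s) - 1) * 20 / length(s)
    half <- fr <= 10
    sum(p[half & fr < 0.1]) / sum(p[half])
  }
  expect_lt(oob(rec), oob(msr))
})
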