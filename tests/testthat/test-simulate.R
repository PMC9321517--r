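test_that("static scenes are pure DC along slow time", {
  sc <- scene_config(duration_s = 10, breathing_amp = 0, noise_sigma = 0,
                     clutter_profile = seq(0.5, 2, length.out = 32))
  scene <- simulate_scene(sc)
  for (j in seq_len(n_bins(scene$matrix))) {
    expect_equal(scene$matrix$samples[, j],
                 rep(sc$clutter_profile[j], n_frames(scene$matrix)))
  }
})

test_that("the subject bin carries an exact sinusoid in noiseless scenes", {
  sc <- scene_config(duration_s = 30, breathing_rate_bpm = 15,
                     subject_bin = 10, noise_sigma = 0)
  scene <- simulate_scene(sc)
  tt <- frame_times(scene$matrix)
  expected <- sc$clutter_profile[10] + sin(2 * pi * 0.25 * tt)
  expect_equal(scene$matrix$samples[, 10], expected, tolerance = 1e-12)
  # and the empirical spectrum peaks at bpm/60
  expect_lt(abs(dominant_freq(scene$matrix$samples[, 10], 20) - 0.25),
            20 / n_frames(scene$matrix))
})

test_that("noiseless slow-time variance is confined to the leakage neighbourhood", {
  sc <- scene_config(duration_s = 20, subject_bin = 10, noise_sigma = 0,
                     leak_halfwidth = 2)
  scene <- simulate_scene(sc)
  v <- brute_variance_profile(scene$matrix$samples)
  expect_true(all(v[c(1:7, 13:32)] == 0))
  expect_true(all(v[8:12] > 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  sc <- demo_scene(seed = 5)
  s1 <- simulate_scene(sc)
  s2 <- simulate_scene(sc)
  expect_identical(s1$matrix$samples, s2$matrix$samples)
  expect_identical(s1$truth$movement_mask, s2$truth$movement_mask)
})

test_that("subject-bin variance matches the sinusoid-plus-noise closed form", {
  # var = amp^2/2 + sigma^2 for a sinusoid in white noise
  sc_base <- scene_config(duration_s = 60, breathing_rate_bpm = 15,
                          breathing_amp = 1, noise_sigma = 0.05)
  vars <- vapply(1:50, function(s) {
    sc <- sc_base; sc$rng_seed <- s
    var(simulate_scene(sc)$matrix$samples[, sc$subject_bin])
  }, numeric(1))
  expect_equal(mean(vars), 0.5 * 1^2 + 0.05^2, tolerance = 0.1)
})

test_that("ground truth mirrors the configuration", {
  sc <- demo_scene()
  scene <- simulate_scene(sc)
  expect_equal(scene$truth$breathing_rate_bpm, sc$breathing_rate_bpm)
  expect_equal(scene$truth$subject_bin, sc$subject_bin)
  expect_length(scene$truth$movement_mask, n_frames(scene$matrix))
  tt <- frame_times(scene$matrix)
  expect_equal(scene$truth$movement_mask,
               (tt >= 30 & tt < 60) | (tt >= 120 & tt < 150))
})

test_that("invalid configurations are rejected with descriptive errors", {
  expect_error(scene_config(duration_s = 60, breathing_rate_bpm = 601),
               "Nyquist", class = "sbdar_validation")
  expect_error(scene_config(duration_s = 60, subject_bin = 40,
                            n_range_bins = 32),
               class = "sbdar_validation")
  expect_error(scene_config(duration_s = 60,
                            movement_epochs = list(c(50, 70, 1))),
               class = "sbdar_validation")
  expect_error(scene_config(duration_s = 60, noise_sigma = NaN),
               class = "sbdar_validation")
})

test_that("cohort configurations respect the study conditions", {
  cfgs <- cohort_scene_configs(5, rng_seed = 1)
  expect_length(cfgs, 5)
  for (sc in cfgs) {
    expect_s3_class(sc, "scene_config")
    expect_gte(sc$breathing_rate_bpm, 10)
    expect_lte(sc$breathing_rate_bpm, 25)
    expect_equal(sc$noise_sigma, 0.2)
    expect_length(sc$movement_epochs, 2)
    for (ep in sc$movement_epochs) {
      expect_equal(ep[2] - ep[1], 30)
      expect_equal(ep[1] %% 30, 0)  # aligned to window boundaries
    }
  }
  # deterministic
  cfgs2 <- cohort_scene_configs(5, rng_seed = 1)
  expect_identical(cfgs, cfgs2)
})
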