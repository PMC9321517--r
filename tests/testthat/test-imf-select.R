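test_that("band energy ratios match the Riemann-sum oracle and pure tones", {
  tt <- (0:1199) / 20
  x_in <- sin(2 * pi * 0.3 * tt)
  x_out <- sin(2 * pi * 2.0 * tt)
  expect_gte(energy_ratio(x_in, 20, c(0.2, 0.8)), 0.99)
  expect_lte(energy_ratio(x_out, 20, c(0.2, 0.8)), 0.01)
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(500)
    expect_equal(energy_ratio(x, 20, c(0.2, 0.8)),
                 riemann_energy_ratio(x, 20, c(0.2, 0.8)), tolerance = 1e-9)
  }
  expect_equal(energy_ratio(numeric(100), 20), 0)
  expect_error(energy_ratio(x_in, 20, c(0.2, 11)), class = "sbdar_validation")
})

test_that("the 0.5 selection rule reproduces the published per-subject choices", {
  # energy ratios of IMF 4-7 for 15 overnight subjects, with the
  # hand-derived selection under a boundary-inclusive 0.5 threshold
  ratios <- list(
    c(0.0241, 0.6642, 0.5175, 0.4550), c(0.1725, 0.7565, 0.6546, 0.4040),
    c(0.0495, 0.6554, 0.5013, 0.6563), c(0.2752, 0.6701, 0.5753, 0.0051),
    c(0.1694, 0.7490, 0.5828, 0.2768), c(0.3934, 0.8145, 0.6163, 0.6916),
    c(0.5834, 0.6768, 0.5548, 0.2016), c(0.0545, 0.7918, 0.5246, 0.3457),
    c(0.2868, 0.6443, 0.6721, 0.1725), c(0.5909, 0.7223, 0.5038, 0.0341),
    c(0.0836, 0.7718, 0.6402, 0.0020), c(0.0728, 0.6104, 0.5225, 0.1039),
    c(0.2947, 0.6174, 0.6390, 0.2253), c(0.1167, 0.6145, 0.5879, 0.1146),
    c(0.2936, 0.6250, 0.5956, 0.4659))
  expected <- list(
    c(5, 6), c(5, 6), c(5, 6, 7), c(5, 6), c(5, 6), c(5, 6, 7), c(4, 5, 6),
    c(5, 6), c(5, 6), c(4, 5, 6), c(5, 6), c(5, 6), c(5, 6), c(5, 6),
    c(5, 6))
  for (i in seq_along(ratios)) {
    sel <- select_by_ratio(ratios[[i]], delta_r = 0.5) + 3L  # ratios start at IMF 4
    expect_equal(sel, expected[[i]], info = sprintf("subject %d", i))
  }
})

test_that("selection is boundary-inclusive at exactly 0.5", {
  expect_equal(select_by_ratio(c(0.5, 0.4999, 0.5001)), c(1L, 3L))
})

test_that("reconstruction sums exactly the in-band IMFs", {
  tt <- (0:599) / 20
  in_band <- sin(2 * pi * 0.3 * tt)
  out_band <- sin(2 * pi * 3 * tt)
  imfset <- structure(list(imfs = cbind(out_band, in_band),
                           residue = numeric(600), source = "emd"),
                      class = "imf_set")
  rec <- select_and_reconstruct(imfset, fs = 20)
  expect_equal(rec, in_band, tolerance = 1e-12)

  solo <- structure(list(imfs = cbind(in_band), residue = numeric(600),
                         source = "emd"), class = "imf_set")
  expect_equal(select_and_reconstruct(solo, fs = 20), in_band)

  none <- structure(list(imfs = cbind(out_band), residue = numeric(600),
                         source = "emd"), class = "imf_set")
  expect_error(select_and_reconstruct(none, fs = 20),
               "no respiratory content", class = "sbdar_no_respiration")
})

test_that("an end-to-end decomposition recovers the simulated breathing frequency", {
  scene <- simulate_scene(scene_config(duration_s = 60,
                                       breathing_rate_bpm = 15,
                                       noise_sigma = 0.1, rng_seed = 17))
  cs <- suppress_clutter(scene$matrix)
  vp <- variance_localize(cs$residual)
  series <- dwt_denoise(rowMeans(
    cs$residual$samples[, vp$preserved_width[1]:vp$preserved_width[2],
                        drop = FALSE]))
  dec <- eemd(series, n_trials = 20, noise_sigma_ratio = 0.2, rng_seed = 1)
  breath <- select_and_reconstruct(dec, fs = 20)
  expect_equal(dominant_freq(breath, 20), 0.25,
               tolerance = 20 / length(breath))
})

test_that("both published band presets are available", {
  expect_equal(respiration_band("method"), c(0.2, 0.8))
  expect_equal(respiration_band("results"), c(0.1, 0.35))
})
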