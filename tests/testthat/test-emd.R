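test_that("the decomposition reproduces the input to 1e-10 relative", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(600)
    d <- emd(x)
    recon <- rowSums(cbind(d$imfs, d$residue))
    expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-10)
  }
})

test_that("a monotone ramp yields no IMFs and itself as residue", {
  x <- seq(0, 5, length.out = 100)
  d <- emd(x)
  expect_equal(n_imfs(d), 0)
  expect_equal(d$residue, x)
})

test_that("tone mixtures separate into IMFs ordered from fast to slow", {
  tt <- (0:1199) / 20
  x <- sin(2 * pi * 2 * tt) + sin(2 * pi * 0.25 * tt)
  d <- emd(x)
  expect_gte(n_imfs(d), 2)
  doms <- vapply(seq_len(n_imfs(d)), function(j)
    dominant_freq(d$imfs[, j], 20), numeric(1))
  expect_equal(doms[1], 2, tolerance = 0.1)
  low <- which.min(abs(doms - 0.25))
  expect_equal(doms[low], 0.25, tolerance = 0.05)
  expect_true(all(diff(doms) < 0.1))  # non-increasing up to tolerance
})

test_that("every returned IMF satisfies the extrema/zero-crossing condition", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(400) + sin(2 * pi * 0.3 * (0:399) / 20)
    d <- emd(x)
    for (j in seq_len(n_imfs(d))) {
      imf <- d$imfs[, j]
      ex <- sbdar:::find_extrema(imf)
      n_ext <- length(ex$maxima) + length(ex$minima)
      expect_lte(abs(n_ext - sbdar:::count_zero_crossings(imf)), 1)
    }
  }
})

test_that("eemd degenerates to emd with one noiseless trial and is seed-deterministic", {
  set.seed(10)
  x <- rnorm(300) + sin(2 * pi * 0.25 * (0:299) / 20)
  d0 <- emd(x)
  d1 <- eemd(x, n_trials = 1, noise_sigma_ratio = 0)
  expect_equal(d1$imfs, d0$imfs, tolerance = 1e-12)
  e1 <- eemd(x, n_trials = 20, noise_sigma_ratio = 0.2, rng_seed = 4)
  e2 <- eemd(x, n_trials = 20, noise_sigma_ratio = 0.2, rng_seed = 4)
  expect_identical(e1$imfs, e2$imfs)
})

test_that("eemd converges to emd as the noise amplitude vanishes", {
  set.seed(11)
  x <- sin(2 * pi * 0.25 * (0:599) / 20) + 0.3 * rnorm(600)
  d0 <- emd(x)
  dn <- eemd(x, n_trials = 5, noise_sigma_ratio = 1e-6, rng_seed = 2)
  expect_equal(dim(dn$imfs), dim(d0$imfs))
  expect_lt(max(abs(dn$imfs - d0$imfs)), 1e-4)
})

test_that("the noise ensemble mitigates mode mixing on intermittent signals", {
  # 0.25 Hz carrier with high-frequency bursts on ~10% of samples: the
  # breathing-band energy ratio of the best breathing IMF under eemd
  # should be at least that under plain emd, on average over seeds
  band <- c(0.2, 0.8)
  gains <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      tt <- (0:899) / 20
      x <- sin(2 * pi * 0.25 * tt)
      burst <- rep(FALSE, 900)
      starts <- sample(850, 6)
      for (b in starts) burst[b:(b + 14)] <- TRUE
      x[burst] <- x[burst] + 0.8 * sin(2 * pi * 4 * tt[burst])
      best_ratio <- function(d) {
        if (n_imfs(d) == 0) return(0)
        max(vapply(seq_len(n_imfs(d)), function(j)
          energy_ratio(d$imfs[, j], 20, band), numeric(1)))
      }
      best_ratio(eemd(x, n_trials = 30, noise_sigma_ratio = 0.2,
                      rng_seed = s)) - best_ratio(emd(x))
    })
  }, numeric(1))
  expect_gte(mean(gains), 0)
})
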