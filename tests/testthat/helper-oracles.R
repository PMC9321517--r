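# Independent oracles used across the suite.

# Orthonormal analysis matrix of one periodized DWT step for signal length n:
# rows are the circular shifts (by 2) of the lowpass and highpass filters.
# Built directly from the filter definition, independently of dwt_step().
dwt_step_matrix <- function(n, h, g) {
  half <- n / 2
  W <- matrix(0, nrow = n, ncol = n)
  for (k in seq_len(half)) {
    for (m in seq_along(h)) {
      col <- (2 * (k - 1) + m - 1) %% n + 1
      W[k, col] <- W[k, col] + h[m]
      W[half + k, col] <- W[half + k, col] + g[m]
    }
  }
  W
}

# Brute-force two-pass variance of each fast-time bin.
brute_variance_profile <- function(samples) {
  apply(samples, 2L, function(col) {
    mu <- mean(col)
    sum((col - mu)^2) / (length(col) - 1)
  })
}

# Riemann-sum spectral band-energy ratio over the half spectrum.
riemann_energy_ratio <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  tot <- sum(p[half])
  if (tot == 0) return(0)
  sum(p[half & freq >= band[1] & freq <= band[2]]) / tot
}

# Dominant half-spectrum frequency of a series.
dominant_freq <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2 & freq > 0
  freq[half][which.max(p[half])]
}

# Study-condition scene used by several end-to-end tests.
demo_scene <- function(bpm = 18, seed = 11, duration_s = 180,
                       noise_sigma = 0.2,
                       movement_epochs = list(c(30, 60, 3), c(120, 150, 3))) {
  scene_config(duration_s = duration_s, breathing_rate_bpm = bpm,
               noise_sigma = noise_sigma, movement_epochs = movement_epochs,
               rng_seed = seed)
}

# Fast pipeline settings for unit tests (fewer EEMD trials; the full
# ensemble is exercised in the acceptance suite).
fast_config <- function(...) sbda_config(eemd_trials = 10L, ...)
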