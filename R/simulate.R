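#' Synthetic radar scene configuration
#'
#' Describes a simulated IR-UWB recording of one sleeping subject: a static
#' clutter background, a quasi-sinusoidal breathing modulation of the
#' reflection amplitude at the subject's range bin (leaking into a small
#' triangular neighbourhood of bins), optional aperiodic body-movement
#' epochs, and additive white Gaussian noise. A movement epoch is a seeded
#' Gaussian random walk (a posture shift) applied to every range bin with a
#' random per-bin gain, and the coherent breathing modulation is suspended
#' while it lasts — during macro movement the chest occupies different
#' range cells and its periodic signature is lost.
#'
#' @param duration_s recording length in seconds.
#' @param slow_rate_hz slow-time frame rate in frames per second (default 20,
#'   the X4-class radar digitization rate).
#' @param n_range_bins number of fast-time range bins.
#' @param subject_bin 1-based range bin of the subject's chest.
#' @param breathing_rate_bpm true breathing rate, breaths per minute. The
#'   breathing frequency `breathing_rate_bpm / 60` must lie below the
#'   slow-time Nyquist frequency `slow_rate_hz / 2`.
#' @param breathing_amp peak amplitude of the breathing modulation
#'   (dimensionless reflection-amplitude units).
#' @param clutter_profile numeric vector of length `n_range_bins`: the static
#'   per-bin background amplitude. Default: all ones.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param movement_epochs list of numeric triplets
#'   `c(start_s, end_s, amplitude)`: aperiodic body-movement intervals.
#'   Epochs may overlap; each must lie within `[0, duration_s]`.
#' @param harmonic_ratio relative amplitude of an optional second harmonic of
#'   the chest displacement (default 0); nonzero values exercise the
#'   harmonic-confusion failure mode of naive spectral rate pickers.
#' @param leak_halfwidth half-width (bins) of the triangular spatial leakage
#'   kernel around `subject_bin` (default 2).
#' @param rng_seed integer seed; the same configuration and seed always
#'   produce bit-identical scenes.
#'
#' @return An object of class `scene_config`.
#' @seealso [simulate_scene()]
#' @export
scene_config <- function(duration_s, slow_rate_hz = 20, n_range_bins = 32L,
                         subject_bin = 10L, breathing_rate_bpm = 15,
                         breathing_amp = 1, clutter_profile = NULL,
                         noise_sigma = 0, movement_epochs = list(),
                         harmonic_ratio = 0, leak_halfwidth = 2L,
                         rng_seed = 1L) {
  check_scalar(duration_s, "duration_s", lower = 1e-9)
  check_scalar(slow_rate_hz, "slow_rate_hz", lower = 1e-9)
  check_scalar(n_range_bins, "n_range_bins", lower = 1)
  check_scalar(subject_bin, "subject_bin", lower = 1, upper = n_range_bins)
  check_scalar(breathing_rate_bpm, "breathing_rate_bpm", lower = 1e-9)
  if (breathing_rate_bpm / 60 >= slow_rate_hz / 2) {
    stopf(paste0("breathing frequency %.3g Hz is at or above the slow-time ",
                 "Nyquist frequency %.3g Hz"),
          breathing_rate_bpm / 60, slow_rate_hz / 2,
          class = "sbdar_validation")
  }
  check_scalar(breathing_amp, "breathing_amp", lower = 0)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  check_scalar(harmonic_ratio, "harmonic_ratio", lower = 0)
  check_scalar(leak_halfwidth, "leak_halfwidth", lower = 0)
  if (is.null(clutter_profile)) clutter_profile <- rep(1, n_range_bins)
  if (length(clutter_profile) != n_range_bins ||
      !all(is.finite(clutter_profile))) {
    stopf("`clutter_profile` must be %d finite values", n_range_bins,
          class = "sbdar_validation")
  }
  if (!is.list(movement_epochs)) {
    stopf("`movement_epochs` must be a list of c(start_s, end_s, amplitude)",
          class = "sbdar_validation")
  }
  for (ep in movement_epochs) {
    if (length(ep) != 3L || !all(is.finite(ep))) {
      stopf("each movement epoch must be 3 finite numbers",
            class = "sbdar_validation")
    }
    if (ep[1] < 0 || ep[2] > duration_s || ep[1] >= ep[2]) {
      stopf("movement epoch [%g, %g] must satisfy 0 <= start < end <= %g",
            ep[1], ep[2], duration_s, class = "sbdar_validation")
    }
  }
  check_scalar(rng_seed, "rng_seed")
  structure(
    list(duration_s = duration_s, slow_rate_hz = slow_rate_hz,
         n_range_bins = as.integer(n_range_bins),
         subject_bin = as.integer(subject_bin),
         breathing_rate_bpm = breathing_rate_bpm,
         breathing_amp = breathing_amp, clutter_profile = clutter_profile,
         noise_sigma = noise_sigma, movement_epochs = movement_epochs,
         harmonic_ratio = harmonic_ratio,
         leak_halfwidth = as.integer(leak_halfwidth),
         rng_seed = as.integer(rng_seed)),
    class = "scene_config"
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %.0f s at %g fps, %d bins, subject at bin %d, %.2f bpm, %d movement epoch(s)\n",
    x$duration_s, x$slow_rate_hz, x$n_range_bins, x$subject_bin,
    x$breathing_rate_bpm, length(x$movement_epochs)))
  invisible(x)
}

#' Load a scene configuration from a YAML or key=value file
#'
#' Accepts either a YAML mapping of [scene_config()] arguments (with
#' `movement_epochs` as a list of 3-element sequences) or a flat
#' `key = value` text file for the scalar fields.
#'
#' @param path configuration file path.
#' @return A `scene_config`.
#' @export
scene_config_from_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$movement_epochs)) {
    cfg$movement_epochs <- lapply(cfg$movement_epochs, as.numeric)
  }
  if (!is.null(cfg$clutter_profile)) {
    cfg$clutter_profile <- as.numeric(cfg$clutter_profile)
  }
  do.call(scene_config, cfg)
}

# Triangular spatial leakage kernel, peak 1 at the subject bin.
leak_kernel <- function(halfwidth) {
  d <- seq(-halfwidth, halfwidth)
  list(offsets = d, weights = 1 - abs(d) / (halfwidth + 1))
}

#' Simulate a radar scene
#'
#' Generates the slow-time by fast-time amplitude matrix implied by a
#' [scene_config()] together with its ground truth. The sample at frame `m`
#' and bin `n` is the static clutter amplitude, plus the breathing
#' modulation `breathing_amp * sin(2 pi f m Ts)` (with optional second
#' harmonic) weighted by a triangular kernel centred on `subject_bin`, plus
#' a Gaussian random-walk movement artifact common to all bins during
#' movement epochs, plus white Gaussian noise.
#'
#' @param config a [scene_config()].
#' @return A list with elements `matrix` (a [radar_matrix()]) and `truth`
#'   (class `ground_truth`: `breathing_rate_bpm`, `subject_bin`, and a
#'   per-frame logical `movement_mask`).
#' @examples
#' sc <- scene_config(duration_s = 60, breathing_rate_bpm = 15,
#'                    noise_sigma = 0.05, rng_seed = 7)
#' scene <- simulate_scene(sc)
#' scene$matrix
#' @export
simulate_scene <- function(config) {
  if (!inherits(config, "scene_config")) {
    stopf("`config` must be a scene_config", class = "sbdar_validation")
  }
  fs <- config$slow_rate_hz
  m <- as.integer(round(config$duration_s * fs))
  n <- config$n_range_bins
  tt <- (seq_len(m) - 1) / fs
  f0 <- config$breathing_rate_bpm / 60

  breath <- config$breathing_amp *
    (sin(2 * pi * f0 * tt) +
       config$harmonic_ratio * sin(2 * pi * 2 * f0 * tt))

  # during macro body movement the chest falls into different range cells,
  # so the coherent breathing modulation at the subject bin is suspended
  movement_mask <- rep(FALSE, m)
  for (ep in config$movement_epochs) {
    movement_mask[tt >= ep[1] & tt < ep[2]] <- TRUE
  }
  breath[movement_mask] <- 0

  samples <- matrix(rep(config$clutter_profile, each = m), nrow = m)
  kern <- leak_kernel(config$leak_halfwidth)
  for (i in seq_along(kern$offsets)) {
    b <- config$subject_bin + kern$offsets[i]
    if (b >= 1L && b <= n) {
      samples[, b] <- samples[, b] + kern$weights[i] * breath
    }
  }

  withr::with_seed(config$rng_seed, {
    for (ep in config$movement_epochs) {
      idx <- which(tt >= ep[1] & tt < ep[2])
      if (length(idx) == 0L) next
      # posture-shift artifact: a smooth Gaussian random walk with one
      # increment per second (bodies reposition on a seconds timescale)
      # plus a broadband jerk component, shared across bins with a random
      # per-bin gain (reflections at different ranges see the shift with
      # different strength)
      len <- length(idx)
      n_steps <- max(2L, as.integer(ceiling(len / fs)))
      smooth <- stats::approx(
        x = seq(0, 1, length.out = n_steps + 1L),
        y = c(0, cumsum(rnorm(n_steps))) / sqrt(n_steps),
        xout = seq(0, 1, length.out = len))$y
      # bridge the walk back to zero: the body returns to rest, so the
      # artifact stays confined to its epoch instead of leaving a
      # permanent clutter offset
      smooth <- smooth - seq(0, 1, length.out = len) * smooth[len]
      walk <- ep[3] * (smooth + 0.15 * rnorm(len))
      gains <- runif(n, 0.5, 1.5)
      samples[idx, ] <- samples[idx, ] + outer(walk, gains)
    }
    if (config$noise_sigma > 0) {
      samples <- samples + matrix(rnorm(m * n, sd = config$noise_sigma), m, n)
    }
  })

  truth <- structure(
    list(breathing_rate_bpm = config$breathing_rate_bpm,
         subject_bin = config$subject_bin, movement_mask = movement_mask),
    class = "ground_truth"
  )
  list(matrix = radar_matrix(samples, slow_period_s = 1 / fs), truth = truth)
}

#' Synthetic sleep cohort
#'
#' Builds a list of seeded [scene_config()]s emulating an overnight cohort:
#' each scene has a breathing rate drawn uniformly from `bpm_range`, a random
#' subject bin and clutter profile, additive noise, and `n_epochs` 30-second
#' body-movement epochs aligned to 30-second analysis windows.
#'
#' @param n_scenes number of scenes (subjects).
#' @param rng_seed integer master seed; every scene derives its own seed.
#' @param duration_s per-scene duration (default 300 s = ten 30-s windows).
#' @param bpm_range range the true rates are drawn from (default 10-25 bpm,
#'   spanning bradypnea through tachypnea).
#' @param noise_sigma additive noise standard deviation (default 0.2).
#' @param movement_amp movement-artifact amplitude (default 3, i.e. macro
#'   body movement three times the breathing modulation).
#' @param n_epochs movement epochs per scene (default 2).
#' @param n_range_bins fast-time bins per scene (default 32).
#' @return list of `scene_config` objects.
#' @export
cohort_scene_configs <- function(n_scenes, rng_seed, duration_s = 300,
                                 bpm_range = c(10, 25), noise_sigma = 0.2,
                                 movement_amp = 3, n_epochs = 2L,
                                 n_range_bins = 32L) {
  check_scalar(n_scenes, "n_scenes", lower = 1)
  n_windows <- floor(duration_s / 30)
  if (n_epochs > n_windows) {
    stopf("cannot place %d epochs in %d windows", n_epochs, n_windows,
          class = "sbdar_validation")
  }
  withr::with_seed(derive_seed(rng_seed, "cohort"), {
    lapply(seq_len(n_scenes), function(i) {
      bpm <- runif(1, bpm_range[1], bpm_range[2])
      bin <- sample(seq(4L, n_range_bins - 3L), 1L)
      prof <- runif(n_range_bins, 0.5, 2)
      wins <- sample(seq_len(n_windows) - 1L, n_epochs)
      epochs <- lapply(wins, function(w) c(w * 30, (w + 1) * 30, movement_amp))
      scene_config(duration_s = duration_s, n_range_bins = n_range_bins,
                   subject_bin = bin, breathing_rate_bpm = bpm,
                   breathing_amp = 1, clutter_profile = prof,
                   noise_sigma = noise_sigma, movement_epochs = epochs,
                   rng_seed = derive_seed(rng_seed * 1000 + i, "scene"))
    })
  })
}
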