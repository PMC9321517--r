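#' Gate slow-time windows by sinusoidal goodness of fit
#'
#' Segments the slow-time series into fixed-length windows, fits the
#' sinusoidal series model to each ([fit_sine_series()]), and keeps only
#' windows whose R-squared reaches the gate threshold. Quasi-sinusoidal
#' chest motion scores high; aperiodic macro body movement scores low and is
#' rejected, so downstream rate estimation sees only breathing-dominated
#' segments. A trailing partial window is dropped. The gate is
#' boundary-inclusive (`R^2 >= r2_threshold` keeps the window) and a window
#' is kept only when its fit converged.
#'
#' @param signal numeric slow-time series (typically the denoised localized
#'   series), at least one window long.
#' @param fs slow-time sampling rate in Hz.
#' @param window_s window length in seconds (default 30).
#' @param n_terms sine terms per fit (default 1).
#' @param r2_threshold gate value in `[0, 1]` (default 0.5).
#' @param overlap_fraction fractional overlap between consecutive windows,
#'   in `[0, 1)` (default 0: disjoint tiling).
#' @return object of class `gate_mask`: `windows` (data frame with
#'   `window`, `start_frame`, `end_frame`, `start_s`, `end_s`, `r_squared`,
#'   `keep`), `fits` (list of `sine_fit`), and the gate parameters.
#' @export
gate_windows <- function(signal, fs, window_s = 30, n_terms = 1L,
                         r2_threshold = 0.5, overlap_fraction = 0) {
  check_scalar(fs, "fs", lower = 1e-9)
  check_scalar(window_s, "window_s", lower = 1e-9)
  check_scalar(r2_threshold, "r2_threshold", lower = 0, upper = 1)
  check_scalar(overlap_fraction, "overlap_fraction", lower = 0, upper = 1 - 1e-9)
  wlen <- as.integer(round(window_s * fs))
  n <- length(signal)
  if (n < wlen) {
    stopf("signal of %d samples is shorter than one %g s window (%d samples)",
          n, window_s, wlen, class = "sbdar_validation")
  }
  step <- max(1L, as.integer(round(wlen * (1 - overlap_fraction))))
  starts <- seq(1L, n - wlen + 1L, by = step)
  fits <- vector("list", length(starts))
  rows <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    i0 <- starts[w]; i1 <- i0 + wlen - 1L
    tt <- (seq(i0, i1) - 1) / fs
    fit <- fit_sine_series(signal[i0:i1], tt, n_terms = n_terms)
    fits[[w]] <- fit
    rows[[w]] <- data.frame(
      window = w, start_frame = i0, end_frame = i1,
      start_s = (i0 - 1) / fs, end_s = i1 / fs,
      r_squared = fit$r_squared,
      keep = fit$converged && fit$r_squared >= r2_threshold
    )
  }
  structure(
    list(windows = do.call(rbind, rows), fits = fits, fs = fs,
         window_s = window_s, r2_threshold = r2_threshold,
         n_terms = n_terms),
    class = "gate_mask"
  )
}

#' @export
print.gate_mask <- function(x, ...) {
  cat(sprintf("<gate_mask> %d window(s) of %g s, gate R^2 >= %.2f: %d kept\n",
              nrow(x$windows), x$window_s, x$r2_threshold,
              sum(x$windows$keep)))
  print(x$windows[, c("window", "start_s", "end_s", "r_squared", "keep")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Concatenate the kept windows of a gated signal
#'
#' @param signal the series that was gated.
#' @param mask a `gate_mask` from [gate_windows()].
#' @return numeric vector: the samples of all kept windows, in order.
#' @export
kept_samples <- function(signal, mask) {
  if (!inherits(mask, "gate_mask")) {
    stopf("`mask` must be a gate_mask", class = "sbdar_validation")
  }
  keep <- mask$windows[mask$windows$keep, , drop = FALSE]
  if (nrow(keep) == 0L) return(numeric(0))
  unlist(lapply(seq_len(nrow(keep)), function(i)
    signal[keep$start_frame[i]:keep$end_frame[i]]), use.names = FALSE)
}
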