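#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the mean of
#' `actual`. By convention a zero-variance `actual` yields 0 (the model
#' reduces to the mean and explains nothing beyond it). Values below 0 are
#' legal and indicate a fit worse than the mean; they fall below any gate
#' threshold in `[0, 1]`.
#'
#' @param actual observed series.
#' @param fitted model predictions, same length (>= 2).
#' @return scalar R-squared, `<= 1` always.
#' @examples
#' r_squared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))  # 0.98
#' @export
r_squared <- function(actual, fitted) {
  if (length(actual) != length(fitted)) {
    stopf("`actual` (%d) and `fitted` (%d) must have equal length",
          length(actual), length(fitted), class = "sbdar_validation")
  }
  if (length(actual) < 2L) {
    stopf("R-squared needs at least 2 points", class = "sbdar_validation")
  }
  ss_tot <- sum((actual - mean(actual))^2)
  ss_res <- sum((actual - fitted)^2)
  if (ss_tot == 0) return(0)
  1 - ss_res / ss_tot
}

# Best least-squares a*sin(w t) + b*cos(w t) + c0 fit to r at fixed angular
# frequency w; the intercept absorbs the DC offset a finite window of a
# sinusoid carries over a non-integer number of periods. Linear, so exact.
sine_ls_at_freq <- function(r, times, omega) {
  X <- cbind(sin(omega * times), cos(omega * times), 1)
  xtx <- crossprod(X)
  if (abs(det(xtx)) < 1e-12) {
    return(list(rss = sum((r - mean(r))^2), a = 0, b = 0, c0 = mean(r),
                fitted = rep(mean(r), length(r))))
  }
  coefs <- solve(xtx, crossprod(X, r))
  fit <- X %*% coefs
  list(rss = sum((r - fit)^2), a = coefs[1], b = coefs[2], c0 = coefs[3],
       fitted = as.numeric(fit))
}

# Candidate frequencies (Hz) from the zero-padded periodogram of r,
# restricted to `band`; returns up to n_peaks local maxima, largest first.
periodogram_peaks <- function(r, fs, band, n_peaks = 3L, n_pad = 4096L) {
  n <- length(r)
  np <- max(n_pad, n)
  r0 <- r - mean(r)
  p <- Mod(fft(c(r0, numeric(np - n))))^2
  freq <- (seq_len(np) - 1) * fs / np
  keep <- which(freq >= band[1] & freq <= band[2] & freq <= fs / 2)
  if (length(keep) == 0L) return(numeric(0))
  pk <- p[keep]
  if (max(pk) <= 0) return(numeric(0))
  is_max <- pk >= c(-Inf, head(pk, -1)) & pk >= c(tail(pk, -1), -Inf)
  cand <- keep[is_max]
  cand <- cand[order(p[cand], decreasing = TRUE)]
  freq[head(cand, n_peaks)]
}

#' Fit a sinusoidal series to a slow-time window
#'
#' Least-squares fit of `y = sum_i alpha_i sin(b_i t + c_i)` used as the
#' periodicity model for breathing motion. Terms are extracted greedily:
#' candidate frequencies are seeded from the top periodogram peaks inside
#' `freq_band`, each candidate is refined by a 1-D search over frequency
#' with amplitude and phase profiled out by linear least squares, and the
#' best term is subtracted before the next is fitted. A final joint
#' Levenberg-Marquardt polish over all parameters (via
#' [minpack.lm::nlsLM()]) is attempted; if it fails the greedy solution is
#' returned. Amplitudes are reported nonnegative with the sign absorbed
#' into the phase.
#'
#' @param window numeric slow-time window, at least `3 * n_terms` finite
#'   samples.
#' @param times sample times in seconds (same length as `window`).
#' @param n_terms number of sine terms (default 1).
#' @param freq_band frequency band (Hz) searched for candidate terms;
#'   default `c(0.05, 1)` brackets human respiration.
#' @return object of class `sine_fit`: `amplitude`, `omega` (rad/s),
#'   `phase`, `fitted`, `r_squared`, `converged`.
#' @examples
#' t <- seq(0, 30, by = 0.05)
#' fit <- fit_sine_series(2 * sin(2 * pi * 0.25 * t + 1), t)
#' fit$r_squared
#' @export
fit_sine_series <- function(window, times, n_terms = 1L,
                            freq_band = c(0.05, 1)) {
  n <- length(window)
  if (length(times) != n) {
    stopf("`window` and `times` must have equal length",
          class = "sbdar_validation")
  }
  if (n < 3L * n_terms) {
    stopf("window of %d samples is too short for %d sine terms (need >= %d)",
          n, n_terms, 3L * n_terms, class = "sbdar_validation")
  }
  if (!all(is.finite(window)) || !all(is.finite(times))) {
    stopf("`window` and `times` must be finite", class = "sbdar_validation")
  }
  fs <- 1 / median(diff(times))
  baseline <- mean(window)
  resid <- window - baseline
  amp <- om <- ph <- numeric(0)

  for (i in seq_len(n_terms)) {
    seeds <- periodogram_peaks(resid, fs, freq_band)
    if (length(seeds) == 0L) break
    df <- fs / 4096
    best <- NULL
    for (f0 in seeds) {
      lo <- max(freq_band[1], f0 - 2 * df)
      hi <- min(freq_band[2], f0 + 2 * df)
      opt <- optimize(function(f) sine_ls_at_freq(resid, times,
                                                  2 * pi * f)$rss,
                      interval = c(lo, hi), tol = 1e-7)
      if (is.null(best) || opt$objective < best$rss) {
        best <- list(f = opt$minimum, rss = opt$objective)
      }
    }
    ls <- sine_ls_at_freq(resid, times, 2 * pi * best$f)
    a_i <- sqrt(ls$a^2 + ls$b^2)
    if (!is.finite(a_i) || a_i == 0) break
    amp <- c(amp, a_i)
    om <- c(om, 2 * pi * best$f)
    ph <- c(ph, atan2(ls$b, ls$a))
    baseline <- baseline + ls$c0
    resid <- resid - ls$fitted
  }

  converged <- length(amp) > 0L
  if (converged) {
    polished <- polish_sine_fit(window, times, amp, om, ph, baseline)
    amp <- polished$amp; om <- polished$om; ph <- polished$ph
    baseline <- polished$baseline
  }
  fitted <- rep(baseline, n)
  for (i in seq_along(amp)) {
    fitted <- fitted + amp[i] * sin(om[i] * times + ph[i])
  }
  structure(
    list(amplitude = amp, omega = om, phase = ph, fitted = fitted,
         r_squared = r_squared(window, fitted), converged = converged,
         n_terms = n_terms),
    class = "sine_fit"
  )
}

# Joint Levenberg-Marquardt refinement of all sine terms plus baseline;
# falls back to the greedy parameters on any failure.
polish_sine_fit <- function(y, times, amp, om, ph, baseline) {
  k <- length(amp)
  start <- as.list(c(amp, om, ph, baseline))
  names(start) <- c(paste0("A", seq_len(k)), paste0("w", seq_len(k)),
                    paste0("p", seq_len(k)), "b0")
  terms <- paste(sprintf("A%d * sin(w%d * t + p%d)", seq_len(k), seq_len(k),
                         seq_len(k)), collapse = " + ")
  fml <- stats::as.formula(paste("y ~ b0 +", terms))
  greedy <- list(amp = amp, om = om, ph = ph, baseline = baseline)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(fml, data = list(y = y, t = times), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL
  )
  if (is.null(fit)) return(greedy)
  cf <- stats::coef(fit)
  a <- cf[paste0("A", seq_len(k))]
  w <- cf[paste0("w", seq_len(k))]
  p <- cf[paste0("p", seq_len(k))]
  b0 <- cf[["b0"]]
  # normalise: nonnegative amplitude, sign folded into phase
  neg <- a < 0
  a[neg] <- -a[neg]
  p[neg] <- p[neg] + pi
  if (!all(is.finite(c(a, w, p, b0)))) return(greedy)
  model <- function(A, W, P, B) {
    B + Reduce(`+`, lapply(seq_along(A), function(i)
      A[i] * sin(W[i] * times + P[i])), numeric(length(y)))
  }
  if (sum((y - model(a, w, p, b0))^2) <=
        sum((y - model(amp, om, ph, baseline))^2)) {
    list(amp = unname(a), om = unname(w), ph = unname(p), baseline = b0)
  } else {
    greedy
  }
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf("<sine_fit> %d term(s), R^2 = %.4f%s\n", length(x$amplitude),
              x$r_squared, if (x$converged) "" else " (not converged)"))
  for (i in seq_along(x$amplitude)) {
    cat(sprintf("  term %d: amplitude %.4g, freq %.4g Hz, phase %.3f rad\n",
                i, x$amplitude[i], x$omega[i] / (2 * pi), x$phase[i]))
  }
  invisible(x)
}
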