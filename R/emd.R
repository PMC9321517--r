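# Indices of local maxima and minima of x. Plateaus contribute their middle
# sample. Endpoints are never extrema here; boundary behaviour is handled by
# mirroring in `envelope_spline`.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  dx <- diff(x)
  s <- sign(dx)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(maxima = integer(0), minima = integer(0)))
  if (length(nz) == n - 1L) {
    # fast path: no flat segments
    ch <- which(s[-1] != s[-(n - 1L)])
    idx <- ch + 1L
    return(list(maxima = idx[s[ch] > 0], minima = idx[s[ch] < 0]))
  }
  # collapse zero runs onto the preceding nonzero slope
  s_f <- s
  last <- 0
  for (i in seq_len(n - 1L)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  turn <- which(s_f[-1] != s_f[-(n - 1L)] & s_f[-(n - 1L)] != 0 &
                  s_f[-1] != 0) + 1L
  if (length(turn) == 0L) return(list(maxima = integer(0), minima = integer(0)))
  # classify each turning point; for plateaus pick the middle sample
  maxima <- integer(0); minima <- integer(0)
  for (i in turn) {
    # i is the sample where the (filled) slope changes sign
    left <- s_f[i - 1L]
    j <- i
    # centre of a flat top/bottom
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    ctr <- as.integer((i + j) / 2)
    if (left > 0) maxima <- c(maxima, ctr) else minima <- c(minima, ctr)
  }
  list(maxima = maxima, minima = minima)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

# Cubic-spline envelope through the extrema at positions `idx`, with up to
# two extrema mirrored across each end of the support 1..n to tame end
# swings.
envelope_spline <- function(idx, vals, n) {
  k <- length(idx)
  take <- seq_len(min(2L, k))
  left_i <- 2 - idx[take]
  left_v <- vals[take]
  take_r <- seq(k, by = -1L, length.out = min(2L, k))
  right_i <- 2 * n - idx[take_r]
  right_v <- vals[take_r]
  xi <- c(rev(left_i), idx, right_i)
  yi <- c(rev(left_v), vals, right_v)
  ok <- !duplicated(xi)
  f <- splinefun(xi[ok], yi[ok], method = "natural")
  f(seq_len(n))
}

# One sifting pass: subtract the mean of the upper and lower cubic-spline
# envelopes until the iterate satisfies the IMF conditions and the
# Cauchy-type SD stopping criterion, or the iteration cap is hit.
sift_imf <- function(r, sd_tol, max_sift) {
  n <- length(r)
  h <- r
  ex <- find_extrema(h)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) {
    return(NULL)  # nothing oscillatory left to extract
  }
  for (it in seq_len(max_sift)) {
    upper <- envelope_spline(ex$maxima, h[ex$maxima], n)
    lower <- envelope_spline(ex$minima, h[ex$minima], n)
    m <- (upper + lower) / 2
    h_new <- h - m
    sd_it <- sum((h - h_new)^2) / (sum(h^2) + .Machine$double.eps)
    ex_new <- find_extrema(h_new)
    n_ext <- length(ex_new$maxima) + length(ex_new$minima)
    # the IMF conditions are checked on the updated iterate, which is what
    # gets returned
    cond <- abs(n_ext - count_zero_crossings(h_new)) <= 1L
    h <- h_new
    ex <- ex_new
    if (sd_it < sd_tol && cond) break
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Adaptively decomposes a signal into intrinsic mode functions (IMFs) plus
#' a residue, `x(t) = sum_i IMF_i(t) + r_n(t)`, by iterative sifting: each
#' IMF is isolated by repeatedly subtracting the mean of the cubic-spline
#' envelopes through the local maxima and minima until (i) the numbers of
#' extrema and zero crossings agree to within one and (ii) the normalized
#' change between sift iterates falls below `sd_tol`. Extraction stops when
#' the residue has fewer than two maxima or minima (is monotone up to
#' trend) or `max_imfs` is reached. IMF 1 carries the highest-frequency
#' oscillation; the residue is computed by subtraction, so the
#' decomposition reproduces the input to floating-point accuracy.
#'
#' @param x numeric signal, length >= 8, finite.
#' @param max_imfs cap on the number of extracted modes (default 10).
#' @param sd_tol Cauchy-type sifting stop tolerance (default 0.2).
#' @param max_sift per-IMF sifting iteration cap (default 50).
#' @return object of class `imf_set`: `imfs` (matrix, one column per IMF;
#'   zero columns for a monotone input), `residue`, `source = "emd"`.
#' @export
emd <- function(x, max_imfs = 10L, sd_tol = 0.2, max_sift = 50L) {
  if (!is.numeric(x) || length(x) < 8L) {
    stopf("`x` must be a numeric signal of length >= 8",
          class = "sbdar_validation")
  }
  if (!all(is.finite(x))) {
    stopf("`x` contains non-finite values", class = "sbdar_validation")
  }
  check_scalar(max_imfs, "max_imfs", lower = 1)
  check_scalar(sd_tol, "sd_tol", lower = 0)
  r <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    imf <- sift_imf(r, sd_tol, max_sift)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1L]] <- imf
    r <- r - imf
  }
  structure(
    list(imfs = if (length(imfs)) do.call(cbind, imfs)
         else matrix(numeric(0), nrow = length(x), ncol = 0L),
         residue = r, source = "emd"),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) of length %d (source: %s)\n",
              ncol(x$imfs), length(x$residue), x$source))
  invisible(x)
}

#' Number of IMFs in an `imf_set`
#' @param x an `imf_set`.
#' @export
n_imfs <- function(x) ncol(x$imfs)

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `n_trials` noise-perturbed copies of the signal (fresh
#' Gaussian white noise of standard deviation
#' `noise_sigma_ratio * sd(x)` per trial) and averages the k-th IMF across
#' the trials that produced it. The noise ensemble decorrelates mode mixing:
#' intermittent high-frequency content no longer leaks into the
#' breathing-scale mode. Modes produced by fewer than half the trials are
#' dropped. Deterministic for a fixed `rng_seed`; with one trial and zero
#' noise the result equals [emd()] exactly.
#'
#' @inheritParams emd
#' @param n_trials ensemble size (default 100).
#' @param noise_sigma_ratio added-noise standard deviation as a fraction of
#'   `sd(x)` (default 0.2).
#' @param rng_seed integer seed for the noise ensemble.
#' @return object of class `imf_set` with `source = "eemd"`; the residue is
#'   `x - rowSums(imfs)`.
#' @export
eemd <- function(x, n_trials = 100L, noise_sigma_ratio = 0.2, rng_seed = 1L,
                 max_imfs = 10L, sd_tol = 0.2, max_sift = 50L) {
  check_scalar(n_trials, "n_trials", lower = 1)
  check_scalar(noise_sigma_ratio, "noise_sigma_ratio", lower = 0)
  n_trials <- as.integer(n_trials)
  sigma <- noise_sigma_ratio * sd(x)
  if (!is.finite(sigma)) sigma <- 0
  n <- length(x)
  trial_imfs <- withr::with_seed(as.integer(rng_seed), {
    lapply(seq_len(n_trials), function(i) {
      noisy <- if (sigma > 0) x + rnorm(n, sd = sigma) else x
      emd(noisy, max_imfs = max_imfs, sd_tol = sd_tol,
          max_sift = max_sift)$imfs
    })
  })
  counts <- vapply(trial_imfs, ncol, integer(1))
  k_max <- max(counts)
  if (k_max == 0L) {
    return(structure(list(imfs = matrix(numeric(0), n, 0L), residue = x,
                          source = "eemd"), class = "imf_set"))
  }
  have_k <- vapply(seq_len(k_max), function(k) sum(counts >= k), integer(1))
  keep_k <- which(have_k >= n_trials / 2)
  imfs <- vapply(keep_k, function(k) {
    cols <- trial_imfs[counts >= k]
    Reduce(`+`, lapply(cols, function(m) m[, k])) / length(cols)
  }, numeric(n))
  imfs <- matrix(imfs, nrow = n)
  structure(
    list(imfs = imfs, residue = x - rowSums(imfs), source = "eemd"),
    class = "imf_set"
  )
}
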