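# Orthonormal Daubechies scaling filters (natural order, sum = sqrt(2)).
# db1 is the Haar pair; dbK has 2K taps and K vanishing moments.
DB_FILTERS <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.8068915093110925, 0.45987750211849154,
          -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db5 = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
          0.0033357252854737712),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  db7 = c(0.07785205408500918, 0.3965393194819173, 0.7291320908462351,
          0.4697822874051931, -0.14390600392856498, -0.22403618499387498,
          0.07130921926683026, 0.08061260915108308, -0.03802993693501441,
          -0.01657454163066688, 0.01255099855609984, 0.0004295779729213665,
          -0.0018016407040474908, 0.00035371379997452024),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953)
)

db_filter_pair <- function(wavelet) {
  if (!wavelet %in% names(DB_FILTERS)) {
    stopf("unknown wavelet '%s'; available: %s", wavelet,
          paste(names(DB_FILTERS), collapse = ", "),
          class = "sbdar_validation")
  }
  h <- DB_FILTERS[[wavelet]]
  len <- length(h)
  # quadrature-mirror highpass: g[m] = (-1)^(m-1) h[len - m + 1]
  g <- rev(h) * (-1)^(seq_len(len) - 1)
  list(h = h, g = g)
}

# Symmetric (half-sample) extension of x at the tail up to length `target`.
reflect_pad <- function(x, target) {
  while (length(x) < target) {
    need <- target - length(x)
    x <- c(x, rev(x)[seq_len(min(need, length(x)))])
  }
  x
}

# One periodized analysis step: x (even length) -> list(approx, detail).
dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n / 2
  a <- numeric(half); d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_along(h)) {
    idx <- (base + m - 1) %% n + 1
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(approx = a, detail = d)
}

# Inverse of dwt_step (transpose of the orthonormal analysis operator).
idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2 * half
  x <- numeric(n)
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_along(h)) {
    idx <- (base + m - 1) %% n + 1
    contrib <- h[m] * a + g[m] * d
    # scatter-add; idx values are unique within one m
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Discrete wavelet transform (periodized orthonormal filter bank)
#'
#' Multi-level decimated DWT with Daubechies filters. Signals whose length
#' is not a multiple of `2^levels` are symmetrically extended to the next
#' multiple before the (periodized) filter bank runs; [idwt()] trims back to
#' the original length, so `idwt(dwt(x))` reproduces `x` to floating-point
#' accuracy.
#'
#' @param x numeric signal.
#' @param wavelet Daubechies family member, `"db1"` ... `"db8"`
#'   (default `"db4"`).
#' @param levels decomposition depth (default 5).
#' @return object of class `dwt_decomposition`: `approx` (coarsest
#'   approximation), `details` (list, element `j` = level-`j` detail
#'   coefficients, level 1 finest), `wavelet`, `levels`, `n_orig`.
#' @export
dwt <- function(x, wavelet = "db4", levels = 5L) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stopf("`x` must be a finite numeric vector", class = "sbdar_validation")
  }
  check_scalar(levels, "levels", lower = 1)
  levels <- as.integer(levels)
  n <- length(x)
  block <- 2L^levels
  if (n < block) {
    stopf("signal of length %d is too short for %d levels; need >= %d samples",
          n, levels, block, class = "sbdar_validation")
  }
  filt <- db_filter_pair(wavelet)
  target <- as.integer(ceiling(n / block) * block)
  xp <- reflect_pad(x, target)
  details <- vector("list", levels)
  a <- xp
  for (j in seq_len(levels)) {
    st <- dwt_step(a, filt$h, filt$g)
    details[[j]] <- st$detail
    a <- st$approx
  }
  structure(list(approx = a, details = details, wavelet = wavelet,
                 levels = levels, n_orig = n),
            class = "dwt_decomposition")
}

#' @rdname dwt
#' @param decomposition a `dwt_decomposition` from [dwt()].
#' @export
idwt <- function(decomposition) {
  if (!inherits(decomposition, "dwt_decomposition")) {
    stopf("`decomposition` must come from dwt()", class = "sbdar_validation")
  }
  filt <- db_filter_pair(decomposition$wavelet)
  a <- decomposition$approx
  for (j in rev(seq_len(decomposition$levels))) {
    a <- idwt_step(a, decomposition$details[[j]], filt$h, filt$g)
  }
  a[seq_len(decomposition$n_orig)]
}

#' Soft thresholding
#'
#' Shrinks coefficients toward zero: values with magnitude below `lambda`
#' are zeroed, the rest move `lambda` closer to zero. A contraction:
#' `|soft_threshold(x, lambda)| <= |x|` elementwise.
#'
#' @param x numeric vector of coefficients.
#' @param lambda nonnegative threshold.
#' @return shrunk coefficients.
#' @export
soft_threshold <- function(x, lambda) {
  check_scalar(lambda, "lambda", lower = 0)
  sign(x) * pmax(abs(x) - lambda, 0)
}

#' Wavelet denoising of a slow-time series
#'
#' Decomposes the series with a 5-level Daubechies DWT, soft-thresholds the
#' detail coefficients of every level, and reconstructs. The noise scale is
#' estimated robustly from the finest detail level only,
#' `sigma = median(|D_1|) / 0.6745`: at a 20 Hz slow-time rate the finest
#' band (5-10 Hz) is far above any respiratory content, so its
#' coefficients are pure noise, whereas coarser bands may carry the
#' breathing line and must not feed the noise estimate. The common
#' threshold `threshold_scale * sigma * sqrt(2 log L)` (the universal
#' threshold for a length-`L` signal) is then applied to every detail
#' level. The median is computed only over coefficients whose slow-time
#' support intersects `active_frames` (the signal-bearing interval;
#' default: all frames). `threshold_scale = 0` disables shrinkage, giving
#' perfect reconstruction.
#'
#' @param signal numeric slow-time series.
#' @param wavelet Daubechies member (default `"db4"`).
#' @param levels decomposition depth (default 5).
#' @param threshold_scale nonnegative multiplier on the per-level threshold
#'   (default 1).
#' @param active_frames optional logical vector (length of `signal`) marking
#'   frames considered signal-bearing when estimating the noise level.
#' @return denoised series of the input length.
#' @export
dwt_denoise <- function(signal, wavelet = "db4", levels = 5L,
                        threshold_scale = 1, active_frames = NULL) {
  check_scalar(threshold_scale, "threshold_scale", lower = 0)
  dec <- dwt(signal, wavelet = wavelet, levels = levels)
  n <- length(signal)
  if (is.null(active_frames)) active_frames <- rep(TRUE, n)
  if (length(active_frames) != n || !is.logical(active_frames)) {
    stopf("`active_frames` must be a logical vector of length %d", n,
          class = "sbdar_validation")
  }
  if (!any(active_frames)) active_frames <- rep(TRUE, n)
  if (threshold_scale > 0) {
    d1 <- dec$details[[1L]]
    # coefficient k at level 1 summarises frames 2k-1, 2k
    act <- vapply(seq_along(d1), function(k) {
      lo <- 2 * (k - 1) + 1
      lo <= n && any(active_frames[lo:min(2 * k, n)])
    }, logical(1))
    if (!any(act)) act <- rep(TRUE, length(d1))
    sigma <- median(abs(d1[act])) / 0.6745
    lambda <- threshold_scale * sigma * sqrt(2 * log(n))
    for (j in seq_len(dec$levels)) {
      dec$details[[j]] <- soft_threshold(dec$details[[j]], lambda)
    }
  }
  idwt(dec)
}
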