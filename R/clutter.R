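#' Recursive static-clutter suppression
#'
#' Removes the static background from a radar recording with the first-order
#' recursive background model, applied independently to each fast-time bin
#' along slow time:
#'
#' \deqn{C(t, \tau) = \alpha \, C(t-1, \tau) + (1 - \alpha) \, x(t, \tau)}
#'
#' where `x` is the raw echo, `C` the running clutter estimate and `alpha`
#' in `[0, 1]` the suppression parameter. `alpha = 1` freezes the clutter at
#' its initial value; `alpha = 0` makes the clutter track the raw echo
#' exactly (zero residual). The residual `x - C` carries the physiological
#' motion.
#'
#' @param x a [radar_matrix()].
#' @param alpha suppression parameter in `[0, 1]` (default 0.97: a slowly
#'   adapting background that passes respiratory frequencies essentially
#'   unattenuated).
#' @param init initial clutter state `C(0, tau)`: `"first-frame"` (default)
#'   uses the first received frame, `"zeros"` starts from an empty
#'   background.
#' @return list with `residual` and `clutter`, both [radar_matrix()] objects
#'   of the input shape.
#' @export
suppress_clutter <- function(x, alpha = 0.97,
                             init = c("first-frame", "zeros")) {
  init <- match.arg(init)
  if (!inherits(x, "radar_matrix")) {
    stopf("`x` must be a radar_matrix", class = "sbdar_validation")
  }
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  s <- x$samples
  c0 <- if (init == "first-frame") s[1L, ] else rep(0, ncol(s))
  clutter <- vapply(seq_len(ncol(s)), function(j) {
    as.numeric(stats::filter((1 - alpha) * s[, j], alpha,
                             method = "recursive", init = c0[j]))
  }, numeric(nrow(s)))
  clutter <- matrix(clutter, nrow = nrow(s))
  list(
    residual = radar_matrix(s - clutter, x$slow_period_s, x$fast_period, x$t0),
    clutter = radar_matrix(clutter, x$slow_period_s, x$fast_period, x$t0)
  )
}

#' Localize the subject by slow-time variance
#'
#' Breathing produces the highest slow-time energy within the detection
#' range, so the subject's range bin is taken as the bin whose
#' clutter-suppressed slow-time series has maximal sample variance (ties
#' break to the lowest index). The contiguous interval around the peak where
#' the variance stays at or above half its maximum (`preserved_width`) is
#' retained for denoising.
#'
#' @param residual a clutter-suppressed [radar_matrix()] with at least two
#'   slow-time frames.
#' @return object of class `variance_profile`: `variance` (per-bin slow-time
#'   variance), `selected_bin`, `preserved_width` (`c(lo, hi)` bin interval)
#'   and `degenerate` (`TRUE` when the scene is perfectly static and no bin
#'   can be selected).
#' @export
variance_localize <- function(residual) {
  if (!inherits(residual, "radar_matrix")) {
    stopf("`residual` must be a radar_matrix", class = "sbdar_validation")
  }
  if (n_frames(residual) < 2L) {
    stopf("variance localization needs at least 2 slow-time frames",
          class = "sbdar_validation")
  }
  v <- apply(residual$samples, 2L, var)
  peak <- max(v)
  if (peak <= 0) {
    return(structure(list(variance = v, selected_bin = NA_integer_,
                          preserved_width = c(NA_integer_, NA_integer_),
                          degenerate = TRUE),
                     class = "variance_profile"))
  }
  sel <- which.max(v)
  lo <- sel
  while (lo > 1L && v[lo - 1L] >= peak / 2) lo <- lo - 1L
  hi <- sel
  while (hi < length(v) && v[hi + 1L] >= peak / 2) hi <- hi + 1L
  structure(list(variance = v, selected_bin = sel,
                 preserved_width = c(lo, hi), degenerate = FALSE),
            class = "variance_profile")
}

#' @export
print.variance_profile <- function(x, ...) {
  if (x$degenerate) {
    cat("<variance_profile> degenerate: zero slow-time variance everywhere\n")
  } else {
    cat(sprintf(
      "<variance_profile> subject at bin %d (var %.3g), preserved width bins %d-%d\n",
      x$selected_bin, x$variance[x$selected_bin],
      x$preserved_width[1], x$preserved_width[2]))
  }
  invisible(x)
}
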