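#' Percentage error of a rate estimate
#'
#' `100 * |candidate - reference| / reference`. Vectorized; the reference
#' is the denominator, so the measure is asymmetric by design and invariant
#' under common rescaling of both arguments.
#'
#' @param candidate_bpm estimated rate(s).
#' @param reference_bpm reference rate(s), strictly positive.
#' @return percentage error(s), nonnegative.
#' @examples
#' percentage_error(15, 16)  # 6.25
#' @export
percentage_error <- function(candidate_bpm, reference_bpm) {
  if (any(!is.finite(reference_bpm)) || any(reference_bpm <= 0)) {
    stopf("`reference_bpm` must be strictly positive and finite",
          class = "sbdar_validation")
  }
  100 * abs(candidate_bpm - reference_bpm) / reference_bpm
}

#' Bland-Altman method agreement
#'
#' For paired rates (candidate vs. reference) computes the per-pair mean
#' and difference, the bias (mean difference), and the 95% limits of
#' agreement `bias +/- 1.96 * SD(differences)` (sample SD). The returned
#' table is plot-ready: per-pair mean on the horizontal axis, difference on
#' the vertical.
#'
#' @param candidate_bpm numeric vector of candidate rates (>= 2).
#' @param reference_bpm numeric vector of reference rates, same length.
#' @return object of class `agreement_report`: `table` (data frame with
#'   `candidate`, `reference`, `mean`, `difference`, `pct_error`), `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `mean_pct_error`.
#' @export
bland_altman <- function(candidate_bpm, reference_bpm) {
  if (length(candidate_bpm) != length(reference_bpm)) {
    stopf("candidate and reference must have equal length",
          class = "sbdar_validation")
  }
  if (length(candidate_bpm) < 2L) {
    stopf("Bland-Altman analysis needs at least 2 pairs",
          class = "sbdar_validation")
  }
  diffs <- candidate_bpm - reference_bpm
  bias <- mean(diffs)
  sd_diff <- sd(diffs)
  tab <- data.frame(
    candidate = candidate_bpm, reference = reference_bpm,
    mean = (candidate_bpm + reference_bpm) / 2, difference = diffs,
    pct_error = percentage_error(candidate_bpm, reference_bpm)
  )
  structure(
    list(table = tab, bias = bias, sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
         mean_pct_error = mean(tab$pct_error)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %d pairs: bias %.3f bpm, LoA [%.3f, %.3f], mean %%error %.2f%%\n",
    nrow(x$table), x$bias, x$loa_low, x$loa_high, x$mean_pct_error))
  invisible(x)
}

#' @export
plot.agreement_report <- function(x, ...) {
  plot(x$table$mean, x$table$difference,
       xlab = "Mean of methods (bpm)", ylab = "Difference (bpm)",
       main = "Bland-Altman agreement", pch = 19, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}
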