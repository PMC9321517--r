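#' Respiration band presets
#'
#' Two frequency bands for scoring intrinsic mode functions against
#' respiratory content, both in common use for adult breathing:
#' `"method"` = 0.2-0.8 Hz (12-48 breaths/min) and `"results"` =
#' 0.1-0.35 Hz (6-21 breaths/min). The end-to-end pipeline default
#' ([sbda_config()]) is the spanning band 0.1-0.8 Hz, which covers
#' bradypnea through tachypnea; see the methods vignette for the rationale.
#'
#' @param preset `"method"` or `"results"`.
#' @return numeric `c(low_hz, high_hz)`.
#' @export
respiration_band <- function(preset = c("method", "results")) {
  switch(match.arg(preset),
         method = c(0.2, 0.8),
         results = c(0.1, 0.35))
}

#' Respiration-band energy ratio of one IMF
#'
#' Fraction of the IMF's spectral energy lying inside the respiration band:
#' `E_rj / E_j`, where `E_j` is the total energy of the magnitude-squared
#' spectrum over `[0, fs/2]` and `E_rj` the energy over `band_hz` (band
#' edges inclusive). A zero-energy IMF scores 0.
#'
#' @param imf numeric series.
#' @param fs sampling rate in Hz.
#' @param band_hz `c(low, high)` in Hz, inside `(0, fs/2)`.
#' @return ratio in `[0, 1]`.
#' @export
energy_ratio <- function(imf, fs, band_hz = respiration_band("method")) {
  check_scalar(fs, "fs", lower = 1e-12)
  if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] >= fs / 2 ||
      band_hz[1] >= band_hz[2]) {
    stopf("`band_hz` must satisfy 0 < low < high < fs/2 = %g", fs / 2,
          class = "sbdar_validation")
  }
  n <- length(imf)
  p <- Mod(fft(imf))^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  e_total <- sum(p[half])
  if (e_total == 0) return(0)
  in_band <- half & freq >= band_hz[1] & freq <= band_hz[2]
  sum(p[in_band]) / e_total
}

#' Select IMF indices by energy ratio
#'
#' The selection rule applied to a vector of respiration-band energy
#' ratios: indices with ratio at or above `delta_r` are selected
#' (boundary-inclusive).
#'
#' @param ratios numeric vector of per-IMF energy ratios.
#' @param delta_r energy threshold (default 0.5).
#' @return integer indices of the selected IMFs.
#' @examples
#' select_by_ratio(c(0.0241, 0.6642, 0.5175, 0.4550))  # 2 and 3
#' @export
select_by_ratio <- function(ratios, delta_r = 0.5) {
  check_scalar(delta_r, "delta_r", lower = 0, upper = 1)
  which(ratios >= delta_r)
}

#' Score and select the respiratory IMFs of a decomposition
#'
#' Computes, for every IMF, the total spectral energy, the energy inside
#' the respiration band, and their ratio, then applies the
#' boundary-inclusive threshold rule ([select_by_ratio()]).
#'
#' @param imfset an [emd()]/[eemd()] result.
#' @param fs sampling rate in Hz.
#' @param band_hz respiration band (default the 0.2-0.8 Hz
#'   [respiration_band()] preset).
#' @param delta_r energy threshold (default 0.5).
#' @return object of class `energy_selection`: `table` (data frame with
#'   `imf`, `energy`, `band_energy`, `ratio`, `selected`), `band_hz`,
#'   `delta_r`, `selected` (integer indices).
#' @export
select_imfs <- function(imfset, fs, band_hz = respiration_band("method"),
                        delta_r = 0.5) {
  if (!inherits(imfset, "imf_set")) {
    stopf("`imfset` must be an imf_set", class = "sbdar_validation")
  }
  k <- n_imfs(imfset)
  if (k == 0L) {
    stopf("the decomposition contains no IMFs", class = "sbdar_validation")
  }
  e_tot <- numeric(k); e_band <- numeric(k); ratio <- numeric(k)
  n <- nrow(imfset$imfs)
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  in_band <- half & freq >= band_hz[1] & freq <= band_hz[2]
  for (j in seq_len(k)) {
    p <- Mod(fft(imfset$imfs[, j]))^2
    e_tot[j] <- sum(p[half])
    e_band[j] <- sum(p[in_band])
    ratio[j] <- if (e_tot[j] > 0) e_band[j] / e_tot[j] else 0
  }
  sel <- select_by_ratio(ratio, delta_r)
  structure(
    list(table = data.frame(imf = seq_len(k), energy = e_tot,
                            band_energy = e_band, ratio = ratio,
                            selected = seq_len(k) %in% sel),
         band_hz = band_hz, delta_r = delta_r, selected = sel),
    class = "energy_selection"
  )
}

#' @export
print.energy_selection <- function(x, ...) {
  cat(sprintf("<energy_selection> band %.2f-%.2f Hz, delta_r = %.2f\n",
              x$band_hz[1], x$band_hz[2], x$delta_r))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Reconstruct the breathing signal from the selected IMFs
#'
#' Sums the IMFs whose respiration-band energy ratio reaches the threshold.
#' An empty selection raises an error naming the remedy (widen the band or
#' lower `delta_r` explicitly) rather than silently returning a
#' non-respiratory signal.
#'
#' @param imfset an [emd()]/[eemd()] result.
#' @param fs sampling rate in Hz.
#' @param selection optional precomputed [select_imfs()] result; computed
#'   from `band_hz`/`delta_r` when missing.
#' @param band_hz,delta_r selection parameters used when `selection` is
#'   missing.
#' @return numeric breathing-signal series.
#' @export
select_and_reconstruct <- function(imfset, fs, selection = NULL,
                                   band_hz = respiration_band("method"),
                                   delta_r = 0.5) {
  if (is.null(selection)) {
    selection <- select_imfs(imfset, fs, band_hz = band_hz,
                             delta_r = delta_r)
  }
  if (length(selection$selected) == 0L) {
    stopf(paste0("no IMF has respiration-band energy ratio >= %.2f in ",
                 "%.2f-%.2f Hz: no respiratory content found (widen ",
                 "`band_hz` or lower `delta_r` explicitly)"),
          selection$delta_r, selection$band_hz[1], selection$band_hz[2],
          class = "sbdar_no_respiration")
  }
  rowSums(imfset$imfs[, selection$selected, drop = FALSE])
}
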