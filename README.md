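# sbdar — sleep breathing detection from IR-UWB radar

Contactless breathing-rate monitoring for sleeping subjects, from the raw
slow-time × fast-time amplitude matrix of an impulse-radio ultra-wideband
(IR-UWB) radar. The package is aimed at researchers in non-contact
vital-sign monitoring who need the full detection chain, its classical
comparison baselines, the method-agreement statistics, and a ground-truthed
scene simulator in one place.

## The method

A radar frame matrix $R_{M\times N}$ (rows = slow-time frames at 20 fps,
columns = range bins) is processed in six stages:

1. **Clutter suppression** — the static background is tracked per bin by
   $C(t,\tau) = \alpha\,C(t-1,\tau) + (1-\alpha)\,x(t,\tau)$ (default
   $\alpha = 0.97$); the residual $x - C$ carries the physiological motion.
2. **Localization** — the subject's bin is the argmax of the residual's
   slow-time variance; the half-maximum width around the peak is preserved
   and averaged into one series.
3. **Denoising** — 5-level Daubechies (`db4`) DWT with soft thresholding
   of the detail coefficients at the universal threshold
   $\hat\sigma\sqrt{2\ln L}$, the noise scale estimated from the finest
   detail band.
4. **Movement gating** — the series is tiled into 30-s windows; each is
   fitted with $y=\sum_i \alpha_i\sin(b_i t + c_i)$ and kept only if
   $R^2 = 1 - SS_{res}/SS_{tot} \ge 0.5$; aperiodic body movement fails
   the gate.
5. **EEMD + IMF selection** — ensemble empirical mode decomposition
   (100 trials, added noise 0.2 × SD) splits each contiguous run of kept
   windows into intrinsic mode functions; IMFs whose respiration-band
   energy ratio $E_{rj}/E_j \ge 0.5$ are summed into the breathing signal.
6. **Rate** — the in-band FFT peak of the reconstructed signal (gap-aware
   over the kept windows' true time stamps, sub-bin interpolated), in
   breaths per minute.

Two classical baselines (autocorrelation + FFT; mean subtraction + FFT),
percentage-error and Bland–Altman agreement statistics, and a seeded
radar-scene simulator with ground truth complete the toolkit. The methods
vignette (`vignettes/sbda-methods.Rmd`) documents every model, parameter
and design decision.

## Worked example

Simulate two minutes of a subject breathing at 17 bpm with one 30-second
body movement, then run the full chain:

```r
library(sbdar)

sc <- scene_config(duration_s = 120, breathing_rate_bpm = 17,
                   noise_sigma = 0.2, subject_bin = 12,
                   movement_epochs = list(c(60, 90, 3)), rng_seed = 8)
scene <- simulate_scene(sc)
scene$matrix
#> <radar_matrix> 2400 slow-time frames x 32 range bins (120.0 s at 20 fps)

res <- run_sbda(scene$matrix, sbda_config(rng_seed = 1))
res$report
#> <sbda_report> 16.99 bpm; bin 12 (width 11-13); IMFs {2,3,4,5}; 3/4 windows kept [1.5 s]
res$estimate
#> <breathing_estimate> 16.99 bpm (peak 0.2832 Hz, band 0.10-0.80 Hz, method: sbda)
```

The chain localized the subject at bin 12, rejected the movement window
(3 of 4 windows kept), and recovered 16.99 bpm against a ground truth of
17 — an error of 0.06 %. Agreement between paired rate measurements is
summarised the standard way:

```r
bland_altman(c(15.2, 17.1, 11.9, 20.3), c(15, 17.5, 12, 20))
#> <agreement_report> 4 pairs: bias 0.000 bpm, LoA [-0.620, 0.620], mean %error 1.49%
```

### Command line

A thin CLI over the same functions lives at `inst/cli/sbda`
(after installation: `system.file("cli", "sbda", package = "sbdar")`):

```sh
sbda simulate  --config scene.yaml --out matrix.csv
sbda gate      --in matrix.csv --out windows.tsv
sbda run       --in matrix.csv --seed 1
sbda evaluate  --in pairs.tsv --out agreement.tsv
```

### Matrix file dialects

*Text*: comma-delimited, one slow-time frame per row, `#`-prefixed
`key=value` header lines (`slow_period_s`, `fast_period`). *Binary*:
little-endian — magic `"SBDR"`, int32 version, int32 M, int32 N, double
`slow_period_s`, double `fast_period`, then M·N doubles row-major.
`read_radar_matrix()` sniffs the dialect.

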