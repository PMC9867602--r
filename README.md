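# mesofiber

Analysis of simultaneous **mesoscale widefield cortical calcium imaging**
(H×W×T movies at 40 Hz through a cranial window) and **striatal fiber
photometry** (two-channel ~1 kHz traces from an implanted fiber). The
package asks, and answers quantitatively: *which cortical activity
patterns are coupled to striatal input, and with what timing?*

It is written for systems neuroscientists working with dual
widefield+photometry preparations, and for anyone who needs a tested,
seeded reference implementation of this analysis chain.

## What it computes

With `F` the raw fluorescence and `F0` a 10-s centered moving average
(or an OLS fit of the 405-nm isosbestic channel), all signals are
normalized as ΔF/F = (F − F0)/F0, band-passed 0.1–12 Hz with a
zero-phase order-2 Chebyshev Type I filter, and photometry is resampled
onto the frame clock (order-8 Chebyshev anti-alias + linear
interpolation). On top of that:

- **Correlation maps** — per-pixel Pearson r between cortex and striatal
  trace, full and partial (controlling for the global cortical signal via
  r_xy·z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²))).
- **Lag maps** — per-pixel cross-correlation lag: r(τ) is re-estimated on
  the overlapping segment at every integer-frame lag in ±2 s; negative
  lag ⇔ cortex leads; pixels with peak r < 0.5 are marked invalid.
- **Motif discovery** — convolutional seq-NMF,
  X ≈ Σₗ W[,,l] H(t−l+1) with W, H ≥ 0 and an optional
  cross-orthogonality penalty, via multiplicative updates (provably
  non-increasing objective at λ = 0). Motif loadings are
  cross-correlated with the striatal trace and scored for spatial
  similarity to the correlation map.
- **Evoked analysis** — stimulus-locked epoching, first-10 vs last-10
  trial habituation ratios, and the activated area (pixels above
  baseline mean + 4·SD, baseline = 1 s pre-stimulus).
- **Synthetic sessions** — a seeded generator that plants travelling
  ("butterfly-like") and disjoint sustained motifs, kernel-convolved
  photometry couplings with exact delays, shared 465/405 drift, noise,
  and a 40-stimulus 10-s-ISI schedule with geometric habituation —
  everything needed for parameter-recovery validation.

See `vignettes/corticostriatal-pipeline.Rmd` for the full methods
account, including the sign and alignment conventions that make planted
delays exactly recoverable.

## Worked example

Generate a 5-minute synthetic session with a sustained cortical motif
whose photometry coupling is a pure 300-ms shift, plus an uncoupled
travelling motif, then run the whole pipeline:

```r
library(mesofiber)

cfg <- scene_config(
  height = 32, width = 32, duration_s = 300,
  motifs = list(motif_spec("alm_visual", rate_hz = 0.25, l_frames = 121),
                motif_spec("travelling_blob", rate_hz = 0.25)),
  couplings = list(coupling_spec(motif = 1, delay_ms = 300,
                                 mode = "attack")),
  seed = 7)
ses <- generate_spontaneous_session(cfg)

summary <- run_full_pipeline(ses, pipeline_config(motif_k = 3L,
                                                  motif_iter = 60L))
str(summary$lag_map)
#> List of 5
#>  $ n_valid             : int 149
#>  $ n_masked            : int 685
#>  $ mean_lag_s          : num -0.3
#>  $ mean_lag_anterior_s : num -0.3
#>  $ mean_lag_posterior_s: num -0.3

g  <- zscore_trace(global_signal(preprocess_stack(ses$stack)))
tr <- preprocess_photometry(ses$photometry, 40,
                            t_out = frame_times(ses$stack))
xcorr_lag(g, tr, max_lag = 2)[c("lag", "peak_r")]
#> $lag
#> [1] -0.3
#> $peak_r
#> [1] 0.6109...
```

Reading the numbers: 149 of 685 cortical pixels exceed the r ≥ 0.5
validity threshold — the planted motif's footprint — and every one of
them reads the planted lag of −0.300 s (cortex leads the striatum by
300 ms), as does the global-signal cross-correlation. The per-motif table
(`summary$motifs`) shows the two coupled-footprint factors with map
similarity ≈ 0.83–0.85 versus −0.45 for the uncoupled travelling motif;
their *loading* lags are larger than the pixel lag because loadings mark
deconvolved motif onsets while pixel signals are indicator-convolved —
the same distinction that separates a global-signal lag from a
motif-loading lag in real recordings.

With `run_full_pipeline(..., out_dir = "out")` the maps (CSV + PNG),
per-motif table, evoked summary, provenance log and a machine-readable
`summary.json` (including the configuration and its MD5) are written to
disk.

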