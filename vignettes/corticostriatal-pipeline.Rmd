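---
title: "Multiscale corticostriatal analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale corticostriatal analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mesoscale widefield calcium imaging records the whole dorsal cortical
surface of a GCaMP-expressing mouse as an `H x W x T` movie at 40 Hz, but
it cannot see subcortical structures. Fiber photometry records a single
bulk fluorescence trace from a deep target — here, corticostriatal axon
terminals in the dorsal striatum — at ~1 kHz through an implanted fiber,
with a calcium-dependent (465 nm) and a calcium-insensitive isosbestic
(405 nm) excitation channel. Recording both simultaneously lets one ask
which cortical activity patterns drive striatal input, and with what
timing.

`mesofiber` implements the analysis chain for such sessions: per-pixel and
per-trace dF/F normalization, zero-phase temporal filtering, pixel-wise
full and partial correlation maps against the striatal trace, per-pixel
cross-correlation lag maps, convolutional sequential NMF (seq-NMF) motif
discovery with motif–photometry cross-correlation, and stimulus-evoked
habituation statistics. A seeded synthetic-session generator with planted
ground truth provides the validation substrate.

# Preprocessing

## dF/F

Both movie pixels and the photometry trace are normalized as
`(F - F0) / F0` with `F0` a centered 10-s moving average (window truncated
at the recording edges so `F0` exists everywhere). Using the same baseline
definition on both modalities means the normalization introduces no
relative distortion between them. For photometry an isosbestic alternative
is provided: `F0 = a * f405 + b` fitted by ordinary least squares, which
removes movement and bleaching artifacts common to both excitation
channels. The moving-average dF/F divides by `F0`; a subtract-only variant
is available behind the `divide` argument for users who prefer raw
`F - F0`.

## Filtering and resampling

Temporal filtering uses a Chebyshev Type I band-pass (order 2, 0.5 dB
ripple, 0.1–12 Hz) applied forward and backward. Zero-phase filtering is
essential here: the whole point of the lag analyses is timing, and a
causal filter would add a frequency-dependent group delay. Because
`signal::filtfilt` applies no padding, sharp low-frequency filters would
otherwise leave long startup transients; the package pads with an odd
(point-reflected) signal extension whose length is derived from the
slowest filter pole before filtering each direction.

Photometry is brought onto the widefield frame clock by an order-8
Chebyshev Type I low-pass (cutoff `0.8 * fs_out / 2`, 0.05 dB ripple,
zero-phase) followed by linear interpolation onto the frame times.

Spatial smoothing is a normalized moving-disc filter of diameter 3 pixels.
The disc footprint includes the diagonal neighbors (center distance
`sqrt(2) <= 1.5`), i.e. the full 3×3 neighborhood; edges use reflected
padding so constants are preserved. The processing order is fixed as
dF/F → spatial smooth → temporal filter and recorded in the output
provenance.

For evoked movies with a stimulus artifact (an LED flash contaminating one
or a few frames), the contaminated frames — supplied explicitly from the
event table, extended by a configurable pad — are replaced by per-pixel
linear interpolation on the raw data before dF/F.

# Correlation and lag maps

The global cortical signal is the spatial mean over the masked cortical
pixels. The full correlation map is the per-pixel Pearson correlation with
the (resampled, z-scored) striatal trace. The partial correlation map
controls for the global signal through the closed form

    r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),

with pixels of zero residual variance set to 0 and flagged; the closed
form is verified against an explicit residual-regression construction in
the tests.

`xcorr_lag` scans integer-sample lags in `[-max_lag, +max_lag]` and
re-estimates the Pearson correlation on the overlapping segment at every
lag, so `|r| <= 1` holds exactly everywhere (an FFT cross-covariance with
global normalization would not guarantee this). The sign convention is
that negative lag means the first signal leads; a cortex-leads-striatum
delay of 300 ms appears as a lag of −0.3 s. Reported lags are integer
multiples of the frame interval — no sub-sample interpolation is
attempted, so a planted delay that is a frame multiple must be recovered
exactly.

The lag map applies this scan per masked pixel. Pixels whose peak
correlation falls below `r_threshold = 0.5` are marked invalid (the "gray"
regions: correlation too low, no detectable peak). The peak search uses
the signed maximum of `r(tau)`, not `|r|`: the maps are
positive-correlation structures, and an anti-correlated peak would be a
biologically different phenomenon. `max_lag` defaults to 2 s, covering the
0.3–0.7 s effects of interest with ample margin. Internally the map is
computed as one pixels-by-lags matrix product per pixel chunk with
running-sum overlap statistics, which keeps the 64×64 × 10-minute case in
the tens of seconds on one CPU.

# Motif discovery

seq-NMF factorizes the masked, rectified (negative dF/F clipped at zero)
pixels-by-time matrix as

    X ~= sum_l W[, , l] H(t - l + 1),    W >= 0, H >= 0,

with `K` motifs of `L = 40` frames (1 s at 40 Hz). The objective is the
squared Frobenius reconstruction error plus `lambda` times a
cross-orthogonality penalty `sum_{k != k'} [(W~'X) S H']_{kk'}`, where
`W~'X` is the transpose convolution of the templates with the data and `S`
smooths over a `(2L-1)`-frame window. The penalty discourages two factors
from explaining the same data at nearby times. Optimization uses
multiplicative updates from a seeded random nonnegative initialization; at
`lambda = 0` the recorded objective is provably non-increasing, which the
tests assert to 1e-9 relative.

Implementation note: every heavy quantity is expressed through the
lagged-loading matrix (`KL x T`, rows are shifted copies of `H`) and the
flattened template matrix (`P x KL`), so one iteration costs a few dense
matrix products and the `P x T` reconstruction is never materialized. This
is what keeps `K = 3`, `L = 40`, 100 iterations on a masked 64×64
10-minute session around three minutes on a single CPU.

Two post-fit conventions matter for timing:

* **Re-centering (during fitting).** Multiplicative updates cannot move
  template mass past a window edge once it hits zero, so fits regularly
  stall with a truncated template flush against the window border. After
  each iteration, each motif's energy center of mass is shifted to the
  middle of its window (counter-shifting its loading), with shifted-in
  frames floored at a small positive value so they can regrow. This is
  reconstruction-preserving except for truncation at the window edge and
  can transiently raise the objective; `recenter = FALSE` restores the
  strictly monotone pure updates.
* **Onset alignment (after fitting).** A convolutional factorization is
  invariant to shifting a template by `s` frames while counter-shifting
  its loading. To remove this arbitrary offset, templates are rotated so
  their first energetic frame (>= 5% of the maximum frame energy) sits at
  window position 1; loadings then mark motif onset. Without this, the
  motif–photometry lag would be biased by a per-fit random shift. The
  residual ambiguity is about one frame, consistent with the general
  caveat that loadings are convolved with the 1-s motif and an exact
  loading delay is not identifiable.

Defaults: `K = 8` (within the 5–10 repeating patterns typical of
mesoscale GCaMP recordings), `L = 40`, `lambda = 0`. The penalty weight is
exposed; for the well-separated synthetic motifs the unpenalized objective
already separates factors, and the monotonicity guarantee at `lambda = 0`
makes it the cleaner default for validation work.

`motif_photometry_xcorr` z-scores each loading row and the trace and
returns per-motif `(lag, peak)` sorted by peak; `motif_map_similarity`
correlates each motif's temporal max-projection with a correlation map
over the masked pixels, which operationalizes the two-class split into
map-like (corticostriatally coupled) and other motifs. Motifs whose
loading energy is below 1e-6 of the largest are reported as empty but kept
in the returned set.

# Evoked analysis

Epochs are cut per event from 1 s before to a configurable time after
onset; events whose window leaves the recording are dropped with a count.
The habituation statistic compares the elementwise average of the first
10 and last 10 trials; each average's amplitude is its post-stimulus peak
after subtracting its own 1-s pre-window mean. With a geometric per-trial
amplitude decay `d`, the expected last/first ratio is
`sum(d^(30:39)) / sum(d^(0:9))`, which the tests verify by direct
summation.

The activated area counts masked pixels whose trial-averaged response
exceeds `mean + 4 SD` of that pixel's pre-stimulus baseline. The
exceedance statistic is the post-stimulus peak per pixel by default
(whether the original analysis used the peak frame or any frame is not
determinable, so `mode = "any"` is also provided). Pixels with zero
baseline variance fall back to the global baseline SD and are flagged.
Behavior motion traces are conditioned with a centered 1-s moving average
followed by z-scoring.

# The synthetic generator

`generate_spontaneous_session` and `generate_evoked_session` build
sessions with the statistical structure the analysis assumes, plus the
planted truth needed for parameter recovery:

* **Motifs.** Two template classes: a bilateral "butterfly-like" pair of
  sensorimotor blobs travelling strictly anterior→posterior across the
  motif window, and a spatially disjoint anterolateral-motor + visual
  pattern whose temporal envelope is the indicator kernel itself.
  Templates are truncated Gaussians (hard zero beyond 2.5 sigma) so
  disjointness is exact. Loadings are homogeneous-Poisson event trains
  thinned so instances never overlap themselves — the sparse,
  non-self-overlapping regime seq-NMF assumes.
* **Photometry.** The 465 channel adds, per coupled motif, the event train
  convolved with a double-exponential indicator kernel (50 ms rise, 1 s
  decay, approximating slow GCaMP kinetics). The kernel is placed so that
  its *peak* sits at the configured delay after the event
  (`mode = "peak"`): a cross-correlation between the impulse-like loading
  and the trace then peaks at exactly minus the planted delay,
  independent of kernel asymmetry and of the anti-alias smoothing applied
  during resampling. (A single-exponential kernel with an instantaneous
  attack was tried first and rejected: after resampling to 40 Hz its
  smoothed attack peaks one frame late, biasing every recovered lag by
  +25 ms.) `mode = "attack"` instead places the kernel onset at the delay;
  combined with the indicator-kernel motif envelope this makes the
  photometry a pure time shift of the footprint pixels, which is the
  correct construction for pixel-level lag-map recovery. The two modes
  exist because "delay between loading and striatum" and "delay between
  pixel signal and striatum" are different quantities whenever the
  cortical signal is itself indicator-convolved.
* **Drift and noise.** A slow sinusoidal drift (default 2% of baseline,
  60-s period) is shared between the 465 and 405 channels, so the
  isosbestic fit has real structure to remove; the 405 channel carries no
  calcium signal. Gaussian noise is added per modality. All draws flow
  from per-component sub-streams derived from one seed in fixed order, so
  enabling noise in one component never perturbs another, and equal
  configurations are bit-identical.
* **Stimulus block.** Forty stimuli at 10-s ISI by default. Each trial
  adds a unilateral posterior response template scaled by
  `habituation_decay^(trial-1)` (default 0.9, a moderately habituating
  response), a coupled photometry transient with the same per-trial
  scaling, and optionally a one-frame full-field artifact spike for
  artifact-removal tests.
* **Uncoupled drive.** An optional smooth photometry component not
  explained by any cortical motif (e.g. thalamic input) is exposed as
  `uncoupled_photometry_sd`; no claim is made about its realism and it
  defaults to zero.

What the generator does *not* emulate: hemodynamic absorption, vascular
anatomy, behavior video, session-to-session registration error, or
non-Gaussian noise. Passing recovery tests on these sessions shows the
estimators are correct under the stated model, not that real recordings
satisfy the model.

# Validation problem sizes

The package's end-to-end checks run at deliberately chosen sizes: global
lag recovery on a 32×32 × 10-minute session; seq-NMF loading-lag recovery
on a masked 64×64 × 10-minute session (`K = 3`, `L = 40`, 100
iterations); lag-map regional recovery on a constructed 64×64×24000 stack
with planted −0.3 s and −0.4 s blocks; epoch bookkeeping on the
40-stimulus schedule; plus closed-form and oracle property suites at
small sizes. Planted delays are frame multiples, so the frame-quantized
estimators are expected to recover them exactly; the seq-NMF loading lag
is expected only to one frame, for the alignment-ambiguity reason above.

# Numerical choices and edge cases

* z-scores use the population (1/N) SD; constant inputs map to zeros, not
  errors, so degenerate pixels propagate harmlessly.
* Moving-average windows shrink at the edges (no NA padding).
* `resample_trace` with `fs_out == fs` is the identity (no filter pass).
* The half-sample-offset case in motif re-centering rounds half up, so a
  template sitting half a frame off-center re-centers instead of sticking.
* Multiplicative-update denominators carry a machine-epsilon floor; exact
  zeros in shifted-in template frames are floored at `1e-6 * max(W)`
  because multiplicative updates cannot regrow exact zeros.
* Stack interchange uses 32-bit float multi-page TIFF with an affine
  transform recorded in a JSON sidecar; round-trip fidelity is float32
  (~1e-7 relative), and photometry/events round-trip through CSV at full
  double precision.

# Known limitations

* Lags are frame-quantized (25 ms at 40 Hz); no sub-sample interpolation.
* The motif-loading delay is identifiable only up to about one frame.
* No hemodynamic correction; no atlas registration (the cortical mask is
  an input); no significance testing of motifs against shuffled data; no
  multiple-testing control across lag-map pixels.
* seq-NMF model selection (choosing `K`) is left to the user; the empty
  motif report helps prune over-specified fits but is not a formal
  selection procedure.
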