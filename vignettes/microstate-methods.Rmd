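---
title: "Microstate analysis methods in mspilot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis methods in mspilot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspilot)
```

`mspilot` analyses multichannel EEG from repeated-session training
protocols through the microstate lens: the recording is segmented into a
symbolic sequence of quasi-stable scalp topographies, and cognitive state is
characterized by the spatial maps themselves, by how the sequence occupies
them (coverage, occurrence, duration), and by the sequence's short- and
long-range temporal dependencies (entropy rate, Hurst exponent). This
vignette explains the models, the parameters that matter, the synthetic
ground truth the package tests itself against, and the numerical and design
choices that were genuinely open.

## The microstate model

At each time point the scalp potential is an `N_S`-vector `V_t` (average
reference, so its entries sum to zero). The model assumes that at any moment
one of `N_K` fixed unit-norm topographies `Γ_k` is active with a signed
intensity `a_kt = Γ_kᵀ V_t`; polarity is not meaningful (the same generator
configuration produces both signs), so all fitting and assignment is done on
squared projections or absolute spatial correlations. The fitted solution
minimizes the residual cost

```
F = (1 / (N_T (N_S − 1))) Σ_t ‖V_t − a_{k(t)t} Γ_{k(t)}‖²
```

with a winner-take-all assignment `k(t) = argmax_k (Γ_kᵀ V_t)²`. Maps are
estimated only at peaks of the global field power (the spatial SD of `V_t`),
where the topography has the best signal-to-noise ratio.

### Modified k-means

The cost is minimized by alternating the assignment above with a map update:
each `Γ_k` becomes the dominant eigenvector of `Σ_{t∈k} V_t V_tᵀ`, which is
the unit-norm minimizer of the within-cluster residual. Iteration stops when
the relative change of `F` drops below `tol = 1e-6` or after 300 iterations;
an empty cluster is re-seeded from a random peak sample. The published
description of this algorithm family states the cost but not the
expectation step; the squared-projection assignment used here is the
standard polarity-invariant reading, and ties are broken toward the lowest
class index so that runs replay deterministically.

Because the cost surface is multimodal, the fit restarts `n_init` times
(default 100, the study setting) from peak samples drawn without
replacement; restart `r` derives its RNG stream from `seed + r − 1`, which
makes best-of-`n` results nested: the best of 10 restarts can only improve
when extended to 100. Restarts are compared on the predictive
cross-validation criterion

```
CV = σ̂² ((N_S − 1) / (N_S − 1 − N_K))²,
σ̂² = Σ_t (V_tᵀV_t − (V_tᵀ Γ_{k(t)})²) / (N_T (N_S − 1))
```

which penalizes model order and is the quantity reported for K-selection
studies; K itself defaults to 7 classes. The GFP²-weighted global explained
variance (GEV) is reported alongside.

### Group maps and labelling

Per-task and per-subject map sets are aggregated by full-permutation
alignment: with the running mean maps as reference, each member set is
assigned, by exhaustive search over all `K!` permutations (5040 at K = 7),
the label order and per-class signs maximizing the mean absolute spatial
correlation; the mean maps are then recomputed as the sign-aligned,
re-normalized average, and the sweep repeats until assignments stabilize.
The objective is non-decreasing by construction and the search is exact, so
no initialization heuristics are needed beyond the first member serving as
the initial reference. Global maps are labelled A–G against a reference
template set by exhaustive optimal one-to-one assignment. The templates
shipped with the package are *synthetic stand-ins* generated by the
package's own topography generator under a fixed seed — they provide a
deterministic, shareable labelling anchor, not published group templates —
and users with montage-matched canonical maps should supply their own.

### Backfitting and parameters

Each cleaned sample (not only GFP peaks) is assigned the class with maximal
absolute spatial correlation; no temporal smoothing of any kind is applied,
because smoothing would alter exactly the temporal statistics studied
downstream. Zero-variance samples cannot be correlated and are excluded.
Coverage is the fraction of labelled time per class, occurrence the number
of uninterrupted runs per second, duration the mean run length in ms.
Boundary (first/last) runs are included by default, which keeps
`coverage = occurrence × duration` an identity per class; a flag excludes
them from the duration average for users who consider truncated runs
unrepresentative.

## Temporal dependencies

**Entropy rate** (bits/sample) measures short-range order: block entropies
`H(k)` of the empirical k-gram distribution are fitted by least squares over
`k = 1..k_max` (default 6) and the slope is the rate estimate; a constant
sequence gives 0 and an i.i.d. uniform K-class sequence `log2 K`. Raw
plug-in block entropies are biased down once `K^k` approaches the sample
count, and the bias grows with `k`, which biases the slope; the package
therefore applies the Grassberger correction to each block entropy, which
keeps the estimate within ±0.02 of the analytic value for i.i.d. 7-class
sequences of 2×10⁵ samples. A difference estimator
(`H(k_max+1) − H(k_max)`) is available as an option. Task-length sequences
(7,500–22,500 samples at 250 Hz) are far below the `10·K^6` guideline for
K = 7, so absolute entropy rates on real-length tasks carry a bias that the
package flags with a warning; within-study contrasts remain meaningful
because all tasks share the estimator and length scale.

**Hurst exponent** measures long-range persistence. The label sequence is
mapped to ±1 under every balanced bipartition of the classes — subsets of
size `⌊K/2⌋`, each subset/complement pair counted once, i.e. all 35
three-versus-four splits for K = 7 (the balanced reading is forced by that
count; unrestricted bipartitions would give 63) — and each mapped sequence
is analysed by detrended fluctuation analysis: cumulative-sum profile,
linear detrending in windows, RMS fluctuation `F(n)` per window size, and
the slope of `log F(n)` vs `log n` as the exponent. Windows are
half-overlapping and ~18 sizes are log-spaced from 10 samples to a quarter
of the sequence; overlapping windows were chosen after observing that
non-overlapping ones leave a small positive bias (~0.02) and more variance
at the 10⁵-sample scale. 0.5 indicates an uncorrelated sequence; the
package's i.i.d. anchor reproduces it within ±0.05.

## The synthetic ground truth

The generator exists so that every stage has a recoverable truth; its
defaults are the study conditions.

* **Topographies**: Gaussian random fields over the sensor positions with a
  squared-exponential covariance (correlation length 1.2 rad of arc),
  centred and normalized; candidates too similar to accepted maps
  (|r| > 0.7) are rejected and redrawn. The length scale gives smooth,
  dipolar-scale patterns, comparable to what spherical splines assume.
* **Sequences**: a semi-Markov chain — uniform transitions with zero
  diagonal plus geometric (memoryless) dwell times, matching the
  quasi-stability of microstates; fixed-length dwells are an option. Default
  mean dwells are 22 samples (88 ms) for Baseline and 18 samples (72 ms) for
  Trial tasks at 250 Hz, inside the classical 60–100 ms range, with the
  Trial model slightly faster to emulate higher state-switching under load.
* **Amplitude**: the rendered GFP follows a rectified 10-Hz sinusoid —
  peaks at ~20/s, the alpha-band convention that makes GFP-peak picking
  meaningful — with a positive floor of 0.3 of the peak (default peak
  10 µV). The floor matters: real GFP troughs never reach zero, and an
  envelope with exact zeros would carry stretches of unclassifiable samples
  that fragment runs at any SNR, contradicting recoverability at high SNR.
* **Noise**: total signal-to-noise power ratio set exactly by `snr_db`
  (default 20 dB). 70% of the noise power is a spatially smooth background
  field *orthogonalized against the template maps* — emulating ongoing
  brain activity outside the microstate subspace, and giving every channel
  realistic neighbourhood correlations even where the seven maps have nodal
  lines — and 30% is white sensor noise, all re-referenced. The
  orthogonalization means the background cannot bias map estimation or
  backfitting.
* **Polarity**: the rendered map sign flips randomly per run, exercising
  the pipeline's polarity invariance.
* **Benchmark ±1 sequences**: for DFA validation the generator produces
  sign-clipped Gaussian processes whose *clipped* autocorrelation equals the
  fractional-Gaussian-noise autocorrelation of the target Hurst exponent
  (the underlying Gaussian correlation is `sin(π ρ/2)`, the arcsine-law
  inverse). Clipping plain fGn instead attains the target only
  asymptotically and measurably undershoots at 10⁵ samples.

What the generator does **not** emulate: volume-conducted artifact
structure (ocular, muscular, cardiac), non-stationary amplitude dynamics,
inter-subject topography variability (all simulated subjects share one map
set), electrode drift, and line noise. Passing recovery tests therefore
demonstrates the correctness of the algorithms under the stated model, not
robustness to every real-world failure mode; the artifact-specific stages
(MARA-style ICA cleaning) are deliberately out of scope, and the pipeline
exposes a no-op hook where such a stage would run.

## Preprocessing choices

* "Flat" means peak-to-peak below 10⁻⁶ µV over a sliding 5-s window (the
  criterion's published form names no amplitude epsilon).
* The neighbourhood-correlation criterion compares each channel with its
  spherical-spline reconstruction from the remaining channels rather than
  with raw pairwise neighbour correlations. With a low-rank topographic
  signal, channels sitting on nodal lines of the map set genuinely
  decorrelate from individual neighbours while remaining perfectly
  predictable from the surrounding field; the reconstruction (a weighted
  neighbour combination, as in RANSAC-style channel cleaning) separates
  such channels (r ≈ 0.87 on clean synthetic data) from truly disconnected
  ones (r ≈ 0). The correlation uses up to 1000 evenly spaced samples.
* The amplitude criterion is a plain z-score of the per-channel SD across
  channels, > 3 flags. Any such threshold rule has a small intrinsic false
  alarm rate over 64 channels; flagged channels are interpolated, not
  dropped, so the cost of a false flag is a smoothed channel.
* FASTER local statistics are z-scored per channel across epochs; any
  |z| > 3 marks an (epoch, channel) for within-epoch spherical-spline
  interpolation, capped at one fifth of the channels per epoch — broader
  artifacts are left for segment rejection, which tests amplitude
  (±100 µV) and the two log-probability criteria (kernel-density estimate
  per channel; epoch-level mean log-probability z < −3 across epochs, or
  group-level mean across channels z < −3). Probability statistics are
  computed *after* local interpolation, matching the published stage order
  (local repair first, segment rejection afterwards); a consequence worth
  knowing is that a large artifact confined to a single channel is repaired
  rather than causing rejection.
* Spherical splines follow the classical scalp-interpolation construction:
  stiffness order m = 4, 7-term Legendre truncation, ridge regularization
  10⁻⁵, with the zero-sum constraint for average-referenced fields.
* Resampling applies a zero-phase Hamming windowed-sinc low-pass at 90% of
  the target Nyquist frequency and evaluates the band-limited signal at the
  exact target times, so the decimation factor need not be an integer and
  in-band amplitudes are preserved within 2%.
* Mastoid referencing is skipped when the montage has no mastoid channels
  (the synthetic montage has none); average reference is applied at
  finalization either way.

## Statistics

The repeated-measures ANOVA handles balanced fully-within designs with one
to three factors. Sums of squares come from the orthogonal
averaging/centering decomposition of the subject × cells array; each within
effect is tested against its interaction with subjects. The
Greenhouse–Geisser ε of every multi-df effect is computed from the
covariance of the subjects' scores on the effect's orthonormal contrasts,
`ε = tr(Σ)² / (df · tr(Σ²))`, clamped to `[1/df, 1]`; both the uncorrected
and the ε-corrected p values are always reported, so "apply the correction
when sphericity is violated" is a presentation decision left to the reader,
and the reported effect size is partial η² = SS/(SS + SS_error), the
convention matching the magnitude of published values in this literature.
The test suite cross-checks F, ε and p against an independent
multivariate-model route (`car::Anova`) to 10⁻⁶, and verifies the
procedure's type-I error on 1000 simulated null datasets. Post-hoc paired t
tests multiply p by the family size (all comparisons generated by the call,
unless overridden) and cap at 1.

## Problem sizes in the test suite

The suite validates at sizes chosen to make sampling error negligible
relative to each tolerance while keeping a laptop-scale run: sequence-level
oracles use 10⁵–2×10⁵ samples; map recovery uses 24 simulated subjects at
16 s each with 8 restarts; the ANOVA null calibration uses 1000 replicates
of a 24-subject 2×3 design; the end-to-end pipeline test runs the full
44-task protocol for one participant with 2 restarts per task. The fitted
defaults (100 restarts, full 22-session protocols) remain the package
defaults for real analyses.

## Known limitations

* The full-permutation alignment is exhaustive and limited to K ≤ 8.
* Entropy rates at task length are biased (shared across conditions);
  absolute values should not be compared across different estimator
  settings or sequence lengths.
* Binary clinical formats (BDF/EDF/FIF) are not parsed; recordings enter
  and leave as CSV + JSON sidecar.
* The ANOVA requires complete balanced designs; missing cells are an error
  rather than an imputation problem.
* Microstate syntax (transition-matrix) analyses beyond the bipartition
  Hurst mapping are out of scope.
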