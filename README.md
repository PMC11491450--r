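# mspilot

EEG microstate analysis for repeated-session training studies, with a fully
verifiable synthetic ground truth.

Ongoing EEG can be described as a sequence of *microstates*: quasi-stable
scalp potential topographies, each lasting tens of milliseconds, that tile
the recording into a symbolic sequence. `mspilot` implements the complete
analysis chain used to monitor cognitive control across a multi-session
simulator training protocol (two task types per session — a short repetitive
Baseline and a longer varied Trial — across three training stages), and a
synthetic-data generator that plants known topographies, label sequences,
entropy rates and Hurst exponents so that every stage of the pipeline can be
validated end to end without access to clinical data.

## What it computes

* **Preprocessing** — zero-phase Hamming windowed-sinc band-pass (1–40 Hz);
  bad-channel detection by three criteria (flat > 5 s, neighbourhood
  correlation < 0.8 against a spherical-spline reconstruction, channel SD
  > 3 SD from the mean); 2-s epoching with FASTER-style local-channel
  statistics (variance, median gradient, amplitude range, deviation from
  mean amplitude) repaired by spherical splines; segment rejection at
  ±100 µV and by single-electrode / electrode-group log-probability;
  average reference and anti-aliased downsampling to 250 Hz.
* **Microstate fitting** — global field power `GFP(t)` (spatial SD of the
  scalp potential), peak selection, and the polarity-invariant modified
  k-means on GFP-peak maps, minimizing

  `F = (1/(N_T (N_S − 1))) Σ_t ‖V_t − Σ_k a_kt Γ_k‖²,  a_kt = Γ_kᵀ V_t`

  over unit-norm maps `Γ_k`, with 100 random restarts scored by the
  predictive cross-validation criterion

  `CV = σ̂² · ((N_S − 1)/(N_S − 1 − N_K))²`,

  plus the GFP²-weighted global explained variance (GEV).
* **Group aggregation** — full-permutation alignment of per-task and
  per-subject map sets (exhaustive K! search per member, sign-aligned mean
  maps) and canonical A–G labelling by optimal one-to-one assignment.
* **Backfitting and parameters** — every sample labelled by maximal absolute
  spatial correlation, no temporal smoothing; per-class coverage
  (fraction of time), occurrence (runs/s) and mean duration (ms), with
  `coverage = occurrence × duration` exact.
* **Temporal dependencies** — finite entropy rate (slope of
  Grassberger-corrected block entropies over k = 1..6, bits/sample) and the
  Hurst exponent by detrended fluctuation analysis of the ±1 sequences from
  all 35 balanced 3-vs-4 bipartitions of the seven classes, averaged.
* **Spectral features** — Welch PSD (2-s Hamming windows, 50% overlap),
  theta band power (4–7.5 Hz), aggregated over five cortical areas.
* **Statistics** — balanced repeated-measures ANOVA (2×3×5, 2×3×7, 2×3
  designs) with Greenhouse–Geisser correction and partial η², and
  Bonferroni-corrected paired post-hoc t tests with `*`/`**`/`***`
  annotations.

## Worked example

```r
library(mspilot)

# ground truth: seven smooth, mutually dissimilar topographies
maps <- generate_template_maps(n_classes = 7, n_channels = 64,
                               max_similarity = 0.7, seed = 1)

# one 20-s task: semi-Markov label sequence rendered to EEG at 20 dB SNR
labels <- sample_label_sequence(sequence_model(7, mean_dwell = 20),
                                n_samples = 5000, fs = 250, seed = 2)
rec <- render_eeg(maps, labels, snr_db = 20, seed = 3)

# fit microstates on GFP peaks, 20 restarts
peaks <- find_gfp_peaks(compute_gfp(rec))
sol <- modified_kmeans(t(rec$data[, peaks]), n_classes = 7, n_init = 20,
                       seed = 4)
sol
#> <microstate_solution> K = 7, cost_F = 0.6138, CV = 0.7768, GEV = 0.994 (20 restarts)

# smoothing-free backfit and the three microstate parameters
seq <- backfit(rec, sol$maps)
microstate_parameters(seq)
#>   class coverage occurrence duration n_runs
#> 1     A    0.117       1.70     68.6     34
#> 2     B    0.182       2.15     84.7     43
#> ...

# recovered labels agree with the planted sequence
m <- spatial_correlation(maps$maps, sol$maps, absolute = TRUE)
perm <- apply(m, 1, which.max)
mean(perm[labels$labels] == seq$labels)
#> [1] 1

# temporal dependencies
suppressWarnings(sequence_dynamics(seq, k_max = 4))
#> <dynamics_result> mean Hurst = 0.966 over 35 partitions, entropy rate = 0.419 bits/sample
```

A GEV near 0.99 and perfect label recovery are expected at 20 dB SNR; the
mean Hurst well above 0.5 reflects the persistence of the planted 80-ms
dwell times, and the low entropy rate the orderliness of the sequence
(an i.i.d. uniform 7-class sequence instead gives log₂7 ≈ 2.81 bits/sample
and Hurst ≈ 0.5).

The full simulate → preprocess → fit → aggregate → backfit → dynamics →
spectral → statistics chain is one call:

```r
res <- run_pipeline(pipeline_config(n_participants = 2, n_init = 10),
                    out_dir = "out/")
```

A thin command-line front-end lives at `inst/cli/mspilot.R`
(`simulate`, `preprocess`, `run-all` subcommands).

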