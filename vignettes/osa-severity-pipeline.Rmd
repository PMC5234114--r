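---
title: "Classifying OSA severity from nocturnal breathing sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying OSA severity from nocturnal breathing sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(osasev)
```

## The problem

Obstructive sleep apnea (OSA) is diagnosed by overnight polysomnography
(PSG), which yields the apnea–hypopnea index (AHI): respiratory events per
hour of sleep. Clinically, AHI < 5 is normal, 5–15 mild, 15–30 moderate, and
≥ 30 severe. PSG is expensive and uncomfortable, so a screening test that
estimates the severity class from something as cheap as a bedside microphone
recording is attractive: apneic pauses, resumed gasps and obstruction-related
snoring all leave acoustic traces.

`osasev` implements a complete severity classifier over single-channel
breathing-sound recordings: denoising, two complementary feature families
(temporal energy transitions and cyclostationary spectral statistics),
wrapper feature selection, and a linear-SVM model evaluated by leave-one-out
cross-validation (LOOCV). Because no patient audio is distributable, the
package also ships a synthetic cohort generator that reproduces the signal
structure the features target, so the whole pipeline is testable end to end.

## Signal model and preprocessing

Recordings are mono WAV at 8 kHz. Analysis is restricted to stage N2/N3
NREM sleep (regular breathing, little movement noise): stage-scored
intervals are mapped to half-open sample ranges
`[round(start*rate), round(end*rate))` and concatenated. Concatenation (as
opposed to per-segment processing) is the default because the downstream
features are whole-night summaries; the stage set is a config key.

Stationary background noise (hiss, hum, ventilation) is removed by
magnitude-domain spectral subtraction: a noise magnitude profile is the mean
spectrum of the 10% lowest-energy STFT frames of the recording itself — in an
unattended recording these frames contain no breath sounds — and each frame's
magnitude becomes `max(|X| - a*N, floor*N)` (phase kept, overlap-add
reconstruction, 512-point periodic Hanning frames at 50% overlap, independent
of the feature framing below). The oversubtraction factor defaults to
`a = 2`: plain mean-magnitude subtraction (`a = 1`) leaves the Rayleigh
residual of the noise magnitudes almost untouched (about 0.34× the input RMS
for matched noise), while `a = 2` attenuates matched noise by more than an
order of magnitude at negligible cost to the foreground. The spectral floor
(1% of the noise magnitude) prevents musical-noise zeros. Subtraction is
clamped so no bin ever exceeds its input magnitude: denoising cannot add
energy.

## Temporal features: energy-level transitions

The time-domain pipeline encodes how breathing-sound energy moves between
four states: silence (1), ordinary breathing (2), loud snoring (3), and
OSA-candidate silence (4).

1. **Framing**: 0.5 s Hanning windows, 80% overlap (0.1 s hop). Trailing
   partial frames are discarded so per-frame statistics are unbiased.
2. **Per-frame quantities**: mean squared-sample energy, the frame's peak
   (maximum squared sample), and the *fill proportion* — the fraction of
   frame energy carried by samples above a silence floor.
3. **Dynamic thresholds**: per 60 s block, the modal bin of a 64-bin
   histogram of log10 *peak* energies estimates the "most frequent energy
   peak range"; the estimate is exponentially smoothed across blocks (factor
   0.9) and scaled by `ratio_low = 2` and `ratio_high = 20` to give the two
   thresholds. The histogram is taken over frame peaks, not mean energies,
   because the thresholds are compared against peaks: a Hanning-weighted
   noise frame's peak-to-mean ratio is roughly 25, so thresholds derived from
   mean energies with these ratios would never classify anything as silence.
4. **Quantization**: level 1 if the peak is at or below the lower threshold
   *or* the fill proportion is below 50%; else level 2 if at or below the
   upper threshold; else level 3. The fill rule exists to suppress "ripple"
   frames whose energy is an accumulation of many tiny values. Its silence
   floor defaults to 25% of the lower threshold: at that height a lone noise
   transient inside an otherwise silent frame fails the 50% fill rule and the
   frame stays silent, so a single spurious sample cannot split a long apneic
   pause in two. (A floor near zero makes the fill proportion of every noisy
   frame ≈ 1 and the rule inert.)
5. **OSA candidates**: every maximal silence run strictly longer than 20 s —
   the clinical marker of a respiratory arrest — whose immediately flanking
   frames are both breathing sounds (levels 2–3, either order) is relabeled
   level 4 in full. Runs touching the recording edges are left alone: without
   both flanks there is no evidence breathing stopped *and* resumed.
6. **Transition matrix**: consecutive-frame transitions are counted into a
   4×4 matrix and normalized globally (all 16 entries sum to 1), so entry
   (1,1) is the overall silence dwell probability — the clinically meaningful
   share of the night spent silent — rather than a row-conditional rate.
   Row-stochastic normalization is available via the config, but global is
   the default. The 16 probabilities, named `t_(i x j)`, are the temporal
   features. Note that transitions (1↔4) are structurally impossible — a
   level-4 run is by construction flanked by levels 2–3 — so those two
   features are always 0 under this rule reading.

## Cyclostationary features

Breathing and snoring are *cyclostationary*: their second-order statistics
repeat at the breath rate (≈ 0.25 Hz) and at snore fundamentals. The cyclic
spectral density (CSD) `S(alpha, f)` — the 2-D Fourier transform of the
time-varying autocorrelation `C(t, tau) = x(t + tau/2) x(t - tau/2)` — is
nonzero off the `alpha = 0` line only for such signals, which makes it a
detector of hidden periodicity that ordinary spectra cannot see.

The estimator evaluates `C` on a grid: 889 time points per 60 s window
(hop ≈ 67.5 ms) and 107 symmetric lags, box-smoothed over one hop around
each grid point, tapered over lags with a Hanning window, then transformed
by an FFT over lags (one-sided, 54 spectral bins up to 2 kHz) and an FFT
over time (889 cyclic-frequency bins, ≈ 1/60 Hz apart). Magnitudes are kept.
Because the time series is real, the upper half of the alpha axis mirrors
the lower half; the two halves are averaged so the symmetry is exact and
argmax queries resolve to the lower alpha. The grid centers are laid out
symmetrically (center *i* and center *n − i + 1* sum to *N + 1*), which
makes the magnitude grid exactly invariant under time reversal of the input.

Per subject, the CSDs of consecutive 60 s windows are folded into a running
(incremental) mean `rms <- rms + (S - rms)/k` — a full night is summarized in
one 54×889 grid with bounded memory; a trailing window shorter than 60 s is
dropped. The grid is mostly near-zero background, so Otsu's method (256-bin
histogram, between-class variance maximization) zeroes sub-threshold entries
while preserving the shape; a constant grid is returned unchanged with a
degenerate flag.

For dimensionality reduction the *transposed* masked grids of all subjects
are concatenated column-wise and factored by non-negative matrix
factorization (`V ≈ WH`, Frobenius objective, Lee–Seung multiplicative
updates, rank 45, at most 500 iterations or a relative objective change
below 1e-6, seeded uniform initialization scaled to `sqrt(mean(V)/rank)`).
Transposing puts the cyclic-frequency axis in the rows, so the shared basis
`W` (889×45) captures the cohort's common cyclostationary patterns. Each
subject's 45×54 activation matrix `H` is then obtained by H-only updates
against the fixed shared `W`. Seven statistics — maximum, minimum, median,
standard deviation (n−1), variance (n−1), kurtosis (`m4/m2²`, non-excess)
and skewness (`m3/m2^1.5`) — over each of the 45 rows and 54 columns give
693 named features (`c_<base>_<obs>_<stat>_<seq>`). Constant rows or columns
have undefined shape statistics; the package defines their skewness and
kurtosis as 0. A mean statistic is available as an optional eighth behind a
config flag but excluded by default: the seven-statistic set is what the
693-feature dimensionality implies. Otsu masking is applied per subject
before merging.

The 54 and 889 step counts are grid-design targets; the package derives its
hop and lag spacing from them rather than the other way around, and both are
config keys.

## Model: selection, SVM, LOOCV

The 709 features (16 + 693) per subject feed a two-stage wrapper selection
scored by stratified 5-fold CV accuracy of a linear SVM: every feature is
ranked by its single-feature CV accuracy, then greedy forward selection runs
within the top-50, stopping when no addition strictly improves the score;
ties break toward the lower feature index, so the whole procedure is
deterministic under a seed.

The classifier is a linear-kernel SVM with one-vs-one pairwise voting over
features min-max scaled to [0, 1] on training data (the scaler travels with
the model, so globally rescaled inputs predict identically). The cost
parameter defaults to `C = 100`, a near-hard-margin setting. This matters at
screening-study sample sizes: with [0, 1] features and a small cost, every
margin constraint sits at its bound whenever the scaled class gap is modest,
the pairwise bias term is then undetermined by the data, and predictions
degrade to majority voting — under LOOCV the held-out subject's own class is
always the minority, which systematically inverts predictions. A large cost
keeps support vectors free and decisions feature-driven; it is a config key
(`model.C`) for users who want the soft-margin behavior.

Evaluation is LOOCV. By default, feature selection runs once on the full
table and the chosen subset is reused in every fold — the workflow in which a
published feature subset precedes classification. This leaks the held-out
subject into the selection step; a strictly nested mode
(`model.nested = TRUE`) reruns selection inside every fold and is the mode
the leakage tests exercise. Scaling and SVM training always use only the
training fold in both modes.

From the 4×4 LOOCV confusion matrix (rows = truth, order
normal/mild/moderate/severe) the package computes per-class TP rate, FP
rate, precision, recall, F-measure, overall accuracy and class-size-weighted
averages; cells with zero denominators are reported as 0 with a flag. The
binary screening view collapses classes to normal (negative) versus any OSA
(positive): a prediction is positive exactly when the predicted class is not
normal. This follows the class labels rather than a literal AHI-5 re-split,
which keeps the binary numbers consistent with the four-class matrix.

## The synthetic cohort

The generator emulates the acoustic structure the features rely on, not
physiology:

* **breathing**: 100–1000 Hz band-passed noise, amplitude-modulated by an
  inhale-burst envelope (40% duty, squared half-sine) with a 4 s breath
  period, plus a low exhale baseline;
* **snoring**: half of the breaths (configurable) carry a 6-harmonic pulse
  train at 80 Hz gated by the same envelope at 2.5× breathing amplitude —
  this injects the cyclostationarity at the breath rate that the CSD
  features detect;
* **apneas**: silent gaps, durations uniform on [15, 40] s so both branches
  of the 20 s rule occur, count Poisson-matched to the target AHI, separated
  by at least two breath cycles;
* **background**: white noise plus 60/120/180 Hz hum at 15 dB below the
  breathing RMS, persisting through gaps (so "silence" is realistic, not
  digital zero).

Cohorts draw class-target AHIs uniformly within each severity band (severe
capped at 60 events/hour) and regenerate a subject until its realized,
Poisson-quantized AHI lands in the intended band. With 10-minute recordings
the realized AHI is a multiple of 6; recordings under ~5 minutes cannot
realize the mild band at all.

What passing tests on this cohort shows: the pipeline detects the acoustic
signatures it was designed for — silence-gap structure and injected
cyclostationarity — under realistic background noise, and its ranking of
severity follows the injected event rates. What it does not show: robustness
to real-world confounds (movement, bed-partner noise, position-dependent
snore spectra, hypopneas that are quiet but not silent), or that the
LOOCV accuracy on real patients would approach the synthetic one; the
synthetic classes are cleanly separated by construction.

## Problem sizes and numerical choices

The shipped evaluation runs 5 subjects per class with 10-minute recordings —
20 subjects, ~3.3 hours of audio — which exercises every stage (a shared
rank-45 basis across 20 transposed grids, selection over 709 features,
20-fold LOOCV) at workstation scale. Determinism: every stochastic step
(synthesis, NMF initialization, fold assignment) derives its seed from the
single pipeline seed; identical inputs and seed give bit-identical feature
tables.

Degenerate inputs are handled explicitly: all-zero threshold blocks leave
the threshold state unchanged; constant matrices skip Otsu with a flag;
zero grids project to zero activations; constant features min-max scale to
0; never-predicted classes yield flagged zero metrics. Threshold ties fall
to the lower energy band; forward-selection ties to the lower feature
index; mirrored CSD alpha bins tie toward the lower alpha.

## Limitations

* The CSD grid spacing reproduces the standard 54×889 shape, but hop and lag
  choices behind such grids are not unique; detection results are insensitive
  to the exact spacing, absolute magnitudes are not.
* Default-mode LOOCV shares the selected subset across folds (see above);
  nested mode is slower but leakage-free.
* The temporal rule cannot see hypopneas (partial obstructions) — they
  reduce, not silence, the airflow sound.
* Snore synthesis is a gated harmonic train; real palatal snores have richer
  jitter/shimmer structure that the NMF basis would have to absorb.
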