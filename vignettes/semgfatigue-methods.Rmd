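---
title: "Methods: sEMG muscle-fatigue classification with semgfatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG muscle-fatigue classification with semgfatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Fatiguing muscle shows two robust surface-EMG signatures: signal
amplitude rises as additional motor units are recruited, and the power
spectrum compresses toward lower frequencies as fiber conduction
velocity falls. `semgfatigue` implements a complete pipeline that turns
multi-channel sEMG recorded during repetitive dynamic exercise (four
upper-limb muscles — biceps brachii, brachioradialis, triceps brachii,
anterior deltoid — at 1000 Hz) into fatigue-level predictions, evaluated
with leakage-safe leave-one-subject-out (LOSO) cross-validation. Two
tasks are supported: binary (no fatigue vs fatigue) and three-class (no
/ moderate / hard fatigue).

Because datasets of this kind are typically private, the package ships a
first-class synthetic cohort generator that reproduces exactly the
statistical structure the pipeline assumes, so every stage is testable
end to end.

## The synthetic cohort: what it emulates and what it does not

`simulate_subject()` produces band-limited Gaussian noise whose
short-time spectrum is a Gaussian bump (width 35 Hz) confined to the
20–450 Hz sEMG band. Two schedules drive the fatigue signature:

* the bump center glides linearly from `mnf_start` (default 120 Hz) to
  `mnf_end` (default 70 Hz) — the spectral-compression signature;
* a slowly varying amplitude envelope scales windowed RMS from
  `baseline_rms` (default 0.05 mV) to `baseline_rms * rms_gain_end`
  (default gain 2), modulated by unit-mean-square repetition bursts at
  the curl cadence (3 s period).

Sessions default to 270 s (the protocol's 4–5 minute sessions). Borg
0–10 ratings of perceived exertion are attached every three repetitions
(9 s), following a monotone trajectory from `borg_start` (0) to
`borg_end` (9) with a per-subject shape exponent; a pre-task baseline
rating is emitted at t = 0. MVC calibration is emulated by three 5-s
maximal-effort segments per channel whose envelope peaks become the
three trial values; their mean is the normalization reference.

Cohorts jitter amplitude (log-normal, σ = 0.15), gain (±10%), the
spectral schedule (±5–6 Hz), session length (±8%) and the Borg shape
exponent (log-normal, σ = 0.2) across subjects, with per-subject random
substreams derived by stable hashing of the subject id so a cohort is
reproducible under reordering. The Borg-shape jitter is what produces
phase/self-report disagreements, and hence conservatively upgraded
labels, at a realistic (~10–15%) rate.

The generator is a *statistical* stand-in: it carries the two
physiological signatures and their inter-subject variability, but no
motor-unit dynamics, force modeling, electrode-motion artifacts, or
power-line interference. A green end-to-end test therefore establishes
that the pipeline recovers the structure it is designed to detect — not
that it would reach any particular accuracy on real recordings.

## Conditioning

Three stages, as is standard for dynamic-contraction sEMG:

1. **Band-pass**: 4th-order Butterworth, 20–450 Hz. The designer builds
   the analog prototype and applies the pre-warped bilinear transform, so
   the −3 dB corners land exactly on the band edges ("4th order" is the
   design order of the low-pass prototype; the band-pass has 8 poles).
2. **Linear envelope**: full-wave rectification followed by a 10 Hz
   low-pass Butterworth; negative ringing is clipped to zero since an
   envelope is non-negative by definition.
3. **MVC normalization**: division by the mean of the three MVC trial
   values, per channel; amplitudes become fractions of MVC.

Filtering is applied forward–backward (zero-phase) with odd edge
extension; the doubled attenuation is accepted in exchange for
undistorted envelope timing. Single-pass filtering is available via
`filter_spec(zero_phase = FALSE)`.

Frequency-domain analysis (features, scalograms) consumes the
band-passed, MVC-normalized signal, *not* the envelope: a 10 Hz envelope
cannot carry 20–450 Hz spectral content, so spectral fatigue indices
computed on it would be meaningless. The envelope is retained for
amplitude inspection and plotting.

## Windowing and the compound label

Recordings are segmented with 2500 ms windows hopped by one tenth
(250 ms). Each window carries the task-progress fraction of its midpoint
and the Borg score of the nearest preceding report (a self-report
describes the effort just performed; windows before any report fall back
to 0). The label combines two ternary readings —

| task progress | Borg | class |
|---|---|---|
| 0–1/3 | 0–2 | NoFatigue |
| 1/3–2/3 | 3–5 | ModerateFatigue |
| 2/3–1 | 6–10 | HardFatigue |

— and on disagreement the **higher** class wins (safety-first upgrade).
`label_source` records whether a window was consensus-labeled or
upgraded; `consensus_filter()` restricts a dataset to the consensus
subset, and `compare_full_vs_consensus()` quantifies how much the
conservative upgrade inflates apparent performance. Progress bins are
the half-open thirds `[0, 1/3] (1/3, 2/3] (2/3, 1]` — the continuous
reading of the integer-percent table.

The LOSO split is constructed over subjects before any windowing;
because windowing is strictly per-subject, per-subject caches of
windows/features/scalograms are numerically identical to re-windowing
inside each fold, and subject-disjointness is *asserted on segment
provenance* in every fold. A violation is a hard error
(`semg_leakage_error`), never a warning.

## Features

Eight features per channel window, 32 per window in channel-major order
(BB, BRA, TRI, DEL):

* amplitude: RMS, mean absolute value (unit weights), waveform length;
* event counts with a 0.1 (mV or fraction-of-MVC) threshold:
  zero crossings (sign change *and* jump ≥ threshold) and Willison
  amplitude (jump ≥ threshold);
* spectral: mean frequency (spectral centroid), mean power frequency
  (the same centroid in its continuous form — computed identically on
  the periodogram and kept as a separate slot so the 8-feature layout is
  preserved), and median frequency.

The PSD is a Hann-tapered periodogram (Welch averaging available by
configuration), scaled so that `sum(P) * df` equals taper-corrected mean
signal power. The median frequency is the half-power crossing of the
cumulative spectrum with each bin's mass spread over a bin centered on
its frequency and linear interpolation inside the crossing bin; this
makes a single spectral line return its own frequency and two equal
lines return their midpoint, and differs from any estimator by less than
one bin width (0.4 Hz at 2500 samples) on smooth spectra. Zero-power
windows make the spectral features undefined; they are emitted as `NA`
and such windows are dropped (with a count) before model fitting.

## Scalograms

The continuous wavelet transform uses the analytic Morlet wavelet
(center-frequency parameter ω₀ = 6, L2 normalization) on a linear scale
grid 1…256 (256 scales — the conventional reading of "scale value 256",
yielding a 256-row scalogram). The transform is evaluated in the
frequency domain with mirror extension of the window, so edges see
reflected data. The pseudo-frequency of scale *a* is
`f = ω₀ fs / (2π a)`; note scales 1–3 map at or above the Nyquist
frequency where the truncated wavelet loses locality — they carry no
in-band energy and are excluded from locality-sensitive property tests.

Images are rendered by per-image min–max normalization, bilinear
resizing to 224 × 224 (configurable), and a fixed perceptual colormap
(viridis) to produce 3 channels; an all-equal coefficient matrix renders
as a uniform mid-colormap image. Rendering is fully deterministic. For
the texture-feature ablation, 13 Haralick co-occurrence statistics
(averaged over the four standard directions at 32 gray levels) and the 7
Hu invariant moments are computed on the grayscale conversion.

## Classifiers

**Classical baselines** consume the 32-dimensional vectors with fixed,
published hyperparameter sets (one per task): logistic regression
(C = 0.002/0.003, 60/65 iterations, one-vs-rest), random forest
(12/14 trees, depth 15/14, Gini), decision tree (Gini, depth 13/16),
linear SVM (C = 0.3/0.4, 80/75 iterations, one-vs-one) and KNN
(k = 7/8, Euclidean–Minkowski, distance weights). No DSP or ML library
providing these learners is available in the runtime environment, so all
five are implemented in-package: CART with exhaustive Gini splits;
bagging with per-split feature subsampling (mtry = √p) over that CART;
Newton-iterated L2 logistic regression (C maps to 1/λ, intercept
unpenalized); hinge-loss dual coordinate descent for the linear SVM
(`max_iter` counts coordinate sweeps; reaching it before convergence is
reported, as the published budgets intend); and exact distance-weighted
KNN. Margin- and distance-based families z-score features with
training-set statistics; trees use raw features. SVM "probabilities" are
a softmax over one-vs-one votes with a small margin tie-break and are
not calibrated — they order decisions correctly but should not be read
as posteriors.

**The image classifier** is a pluggable convolutional backbone plus the
dense head: global average pooling → dense 256 → dropout 0.4 → dense 128
→ dropout 0.4 → softmax (2 or 3 units), trained with Adam at learning
rate 0.002, batch size 128, 70 epochs by default, no early stopping. The
four ImageNet-scale backbone identifiers are recognized but error
unless weights are locally available; the default backbone is a small
scratch CNN (three 3×3 conv + 2×2 max-pool blocks, widths 16/32/64,
feature width 64) implemented in plain R (convolutions as nine shifted
BLAS products; gradients verified against numerical differentiation).
The scratch backbone appends a normalized row-coordinate plane to its
input: scalogram rows are scales, and after global average pooling the
network would otherwise be largely blind to the *position* of the
spectral ridge — the principal subject-invariant fatigue cue once
per-image normalization has removed absolute amplitude. One seed
controls initialization, shuffling, dropout masks and the 10% stratified
validation split used for the per-epoch loss/accuracy curves.

## Evaluation

`run_loso()` executes the full pipeline per fold and reports per-fold
and aggregate (mean ± sd over folds) accuracy, precision, recall and F1,
a fold-summed confusion matrix, and pooled one-vs-rest ROC and
precision–recall curves (trapezoid and step-interpolated AUCs). With
more than two classes the single printed precision/recall/F1 values are
unweighted macro averages (recorded in the report); per-class values are
kept alongside. Undefined per-class metrics (empty class in a fold) are
excluded from macro averages with a count. Accuracy is trace/total; the
one-vs-rest micro form that also credits true negatives is computed as
`accuracy_ovr` — the two coincide exactly for two classes, and both are
reported because the printed accuracy equation in the source study is of
the micro form while its two-class tables are consistent with either.

## Numerical and scaling choices

* Butterworth coefficients were verified coefficient-exact against an
  independent reference implementation during development; the −3 dB
  corner property is asserted in the tests from the designed transfer
  function itself.
* The end-to-end acceptance run scales the stated world down to desk
  size: 5 subjects, 60 s sessions (the generator default stays 270 s).
  The feature/random-forest arm runs at the published 2500/250 ms
  windowing; the image arm runs at hop 1250 ms, 64 CWT scales, 32 px
  images and 12 epochs at the published learning rate and batch size,
  chosen once for the reduced problem size and CPU budget.
* Ties in predicted probabilities resolve toward the lower-ordered
  (less fatigued) class, making the tie-break explicit and testable.

## Known limitations

* The generator's spectral bump is symmetric and stationary within 1 s
  synthesis chunks; real sEMG spectra are skewed and nonstationary
  within repetitions.
* The scratch CNN is deliberately small; it demonstrates that the
  scalogram representation carries the fatigue signal, not what an
  ImageNet-scale fine-tuned backbone would achieve.
* SVM pseudo-probabilities are uncalibrated (see above); ROC/PR curves
  for the SVM family should be interpreted with that in mind.
* Published accuracy tables from the source study's private cohort are
  out of scope by design; no result in this package should be compared
  against them directly.
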