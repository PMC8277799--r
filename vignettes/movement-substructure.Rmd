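---
title: "Movement sub-structure of rotarod trials: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement sub-structure of rotarod trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotakin)
```

## The problem

Time-to-fall off an accelerating rotarod is the standard scalar readout of
rodent motor performance, but it discards everything that happens between
mounting and falling. When the paw of a mouse is video-tracked during the
trial, the resulting (t, x, y) trajectory carries a *movement
sub-structure*: how regularly the paw steps, how smoothly its speed evolves
as the rod accelerates, how the stance is adjusted. rotakin quantifies that
sub-structure and relates it to the trial outcome. The intended users are
behavioral neuroscientists who already export paw coordinates from tracking
software and want per-trial kinematic features, early-window predictors of
the final score, group statistics, and an intra-trial early-versus-late
classifier.

## The measurement model

A trial is a calibrated trajectory sampled at 15 or 30 Hz, in inches, with
the origin at the lower-left of the rod area (y up, x rightward). All
analysis runs at a common 15 Hz: higher-rate recordings are downsampled
with a zero-phase FIR low-pass (forward-backward filtering with reflective
edge padding) before cubic-spline evaluation on the uniform target grid, so
no phase lag is introduced and content above the new Nyquist frequency is
removed. Velocity and acceleration are second-order central differences
(one-sided at the endpoints); central differences were chosen for their
symmetric lag and exactness on linear trends. Negative vertical velocity
means downward paw motion; "speed" always denotes the absolute value.

## The feature catalog

Per axis (vertical, horizontal) and per window (whole trial, or the first T
seconds), `compute_features()` reports:

* **mean_pos, mean_vel, mean_speed, mean_acc** — positional and kinematic
  means (inches, in/s, in/s²); velocity and acceleration are signed.
* **variance_pos** — population variance (divide by N) of position;
  **mad_pos** — unscaled median absolute deviation. Neither estimator is
  stated in the source methods; population variance and the unscaled MAD
  are the conventional descriptive choices and both are exposed as plain
  columns rather than hidden normalizations.
* **apen_pos** — approximate entropy of position: the Pincus statistic
  `Phi_m − Phi_{m+1}` with Chebyshev distance and self-matches included.
  Defaults m = 2, r = 0.2·SD are the classic physiological-signal settings
  (also used by the treadmill-gait literature this analysis descends from);
  they are configurable via `apen_params()`. Because r scales with the SD,
  ApEn is invariant to affine rescaling of the trace. A periodic saw-tooth
  scores low; irregular stepping scores high.
* **sparc_speed, sparc_acc** — spectral arc length of the absolute speed
  (and acceleration-magnitude) profile: the negated arc length of the
  normalized magnitude spectrum over a low-frequency band. Values are
  always ≤ 0 and closer to zero means smoother movement. The band runs
  from 0 Hz to the smaller of 10 Hz and (adaptively) the highest frequency
  whose normalized magnitude exceeds 0.05, the defaults of the
  human-movement smoothness literature; whether the original analysis used
  the adaptive rule or a fixed band cannot be determined from its text, so
  both are exposed via `sparc_params(adaptive = )`.

`first_t_feature()` computes any catalog feature on the first T seconds
(T ≥ 8, the first rod-speed increment). The window is closed at its right
edge so that T equal to the trial duration reproduces the whole-trial
value exactly.

## Early-predictor scan

`scan_early_predictors()` computes a feature over cumulative segments
T = 8, 9, 10, … s and Spearman-correlates each against time-to-fall.
Spearman's rho uses average ranks; the two-sided p-value is the
t approximation on n − 2 degrees of freedom, replaced by the exact
full-permutation p for n ≤ 9 because the smallest subset analyses this
supports use n = 9 (at that size the enumeration over 9! permutations is
instant and the t approximation is at its weakest). By default a mouse
leaves the scan when T exceeds its fall time (`cohort_rule = "drop"`,
cohort size non-increasing in T); `"truncate"` instead stops the scan at
the shortest fall time so every point uses the full cohort. The default
scan ceiling is 30 s — the floor every tested animal reaches — and is
configurable. No multiple-testing correction is applied across T or across
features; p-values are reported raw, and users comparing many features
should correct downstream.

## Per-second bins, outlier zeroing and smoothing

For the classifier, features are computed per one-second bin `[k, k+1)`
from trial start; the last 5 s before the fall are always excluded so a
falling mouse cannot contaminate the series, and the partial trailing bin
is dropped. One-second bins produce occasional extreme values, which are
handled by the literal zeroing rule: any value more than 6 median absolute
deviations (unscaled, about the median) from the series median is replaced
by zero, and the zeros are *kept* in downstream statistics. When the MAD
collapses to zero on non-constant data the rule stays literal — anything
off the median is beyond the threshold — because that is the only reading
under which a single gross outlier in an otherwise constant series is
zeroed; the alternative readings (`unit = "mean_ad"`, `unit = "sd"`) are
exposed because the source describes the threshold both as "mean absolute
deviations" and as "standard deviations" in different places. The binned
series is then smoothed by locally weighted linear least squares with
tricube weights (lowess with zero robustness iterations, the same
procedure as MATLAB's `smooth`), window 5 bins by default; the span is a
free choice (unstated in the source) and is configurable.

## Early-vs-late classifier

`build_class_dataset()` takes the first 20 one-second bins as the "early"
class and the last 20 usable bins (final 5 s excluded) as "late", with at
most 6 features (≤ 3 per axis) to limit overfitting a 40-row dataset, and
z-scores each column over the 40 rows. `fit_svm_classifier()` then:

1. scores every kernel (linear, Gaussian, polynomial of order 2–4) and
   hyperparameter setting (kernel scale and box constraint on a logarithmic
   grid, 10^−2…10^2) by stratified ten-fold cross-validated
   misclassification;
2. selects the kernel with the lowest CV misclassification, breaking ties
   toward the simpler kernel and then the first grid point;
3. reports the ROC AUC from pooled out-of-fold decision values of a
   *nested* cross-validation, in which each held-out fold is predicted by
   the setting selected on the remaining data alone.

The nested evaluation is a deliberate design choice: pooling decision
values from the same folds that chose the best of ~90 settings inflates
the AUC of indistinguishable classes well above 0.5, which would defeat
the stated interpretation (0.5 = no difference, 1 = two distinct
clusters). With the nested estimator, identically distributed classes
average an AUC near 0.5 while a 6-SD class offset still yields exactly 1.
The polynomial scale grid starts at 10^−1 rather than 10^−2: at scale
0.01 the polynomial kernel matrix on standardized data reaches ~10^20 and
the underlying optimizer stalls at its iteration cap, so that corner is
numerically meaningless. The decision-value orientation is fixed (larger =
"late") and the ROC direction is fixed accordingly, so a null AUC can fall
below 0.5 instead of being folded upward. One classifier is fit per trial,
since the discriminating features are expected to vary across animals.
Reports are bit-reproducible given (dataset, seed).

## Group statistics

`compare_groups()` is the two-tailed Student's t-test (pooled variance by
default, Welch optional), unpaired for independent groups and paired on
matched mouse IDs for trial-1-versus-trial-2 learning contrasts; summaries
are mean ± SEM. `pca_group_separation()` z-scores the feature matrix
(features differ in scale by orders of magnitude), projects onto the first
three principal components, and tests group separation of the scores with
one-way MANOVA Wilks' lambda and its F approximation. Standardizing before
PCA mirrors the standardization applied to the classifier inputs.

## The synthetic generator

No trajectory data are published with the source study, so the package
carries a simulator whose outputs exercise every analysis stage. It
emulates, statistically rather than biomechanically:

* an accelerating rod: 4 RPM + 1 RPM every 8 s to a 40 RPM plateau,
  as discrete steps (a continuous ramp is available for sensitivity
  analysis);
* vertical stepping as a quasi-periodic saw-tooth phase-locked to the rod:
  the paw is carried down with the rod surface for 80% of each cycle and
  re-placed over the last 20%. The finite re-placement phase matters: an
  instantaneous reset sampled at 15 Hz produces single-sample ~9 in/s
  spikes that flatten the speed spectrum and make the smoothness score
  insensitive to everything else. Cadence is 0.8 + 0.05·RPM Hz (about
  1–2.8 Hz, a plausible stepping rate range); amplitude 0.6 in over a
  0.8 in baseline;
* stepping irregularity as multiplicative phase noise with SD
  `vertical_jitter` (0 gives a strictly periodic saw-tooth and minimal
  vertical ApEn; ApEn increases monotonically with the jitter);
* a 5.5 Hz tremor ripple of amplitude `tremor_amp` (default 0.05 in), the
  smoothness dial: more ripple makes sparc_speed more negative;
* downward slip dips (Poisson events, Gaussian shape, 0.35 in deep) and
  0.02 in additive tracking noise;
* horizontal stance adjustment as a 0.5 Hz, 0.25 in sway whose phase
  jitter scales with `1 − horizontal_regularity`, so regular stance timing
  gives low horizontal ApEn. An earlier design with sparse step-like
  stance shifts every ~2 s was abandoned: transitions that rare are
  invisible to length-2 ApEn templates against tracking noise, and the
  statistic did not respond to the regularity dial at all;
* a fall time drawn per second from t = 30 s (the floor every tested
  animal reaches) with hazard `logit⁻¹(−8 + 0.5·RPM − 14·skill)`, capped
  at 300 s as in standard rotarod sessions. The steep coefficients make
  skill the dominant determinant of fall time (rank correlation ≈ 0.94),
  which is what the sign-recovery construction requires: cohorts are
  *built* so that vertical ApEn rises and horizontal ApEn falls with
  time-to-fall (via `default_params_sampler()`, which maps skill ↑ to
  vertical_jitter ↑ and horizontal_regularity ↑), and the analysis stack
  must recover those constructed signs. Nothing about the generator is
  calibrated to real mice — no quantitative paw statistics are published
  to calibrate against — and its amplitudes are order-of-magnitude
  choices, stated here once and not revisited;
* one-trial learning as a fractional reduction (`learning_delta`) of
  jitter, tremor and slip rate in trials 2 and 3, producing smoother and
  more regular movement without forcing a longer time-to-fall.

What passing tests on these cohorts show is that the pipeline *recovers
programmed structure of the kinds the source study reports* — correlation
signs, early-late separability, learning contrasts — at realistic sample
sizes (22 mice; subsets of 9; 20 bins per class). What they cannot show is
anything about real mice: the generator has no limb dynamics, no torque,
no weight effects, and its noise is Gaussian and stationary. Conclusions
about biology require real trajectories.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to keep the statistical
checks well-powered while remaining quick: 100 replicate cohorts of 22
mice for sign recovery, 100 cohorts of 9 mice (two trials) for the
learning contrast and its null, 1000 permuted-score scans for the
false-positive rate, 50 seeds for the null-AUC calibration, and 200 random
series (length ≤ 50) for exact agreement between the ApEn implementation
and a brute-force template-counting oracle. Tolerances: the spectral arc
length matches a direct-DFT, chord-summed oracle to 1e-6 and is
amplitude-scale-invariant to 1e-9; resampling a series to its own rate is
the identity to 1e-9; exact-permutation p-values match enumeration to
1e-12. Degenerate inputs have defined behavior throughout: constant series
have zero ApEn (with a warning), all-tied Spearman inputs return NA with a
warning instead of a silent zero, zero-variance classifier columns are
dropped with a warning, and an all-zero speed profile is an error rather
than a smoothness score.

## Known limitations

* Tracking dropouts (occluded paw) are flagged (gaps > 3 sampling
  intervals) but never imputed; how the original exports handled them is
  unknown.
* The early/late class bins inherit serial correlation from the smoothing
  step; the classifier's CV treats bins as exchangeable within class, as
  the source procedure does.
* The per-bin feature median uses whatever samples fall in the bin
  (15 at the analysis rate); bins at the usable-region edge are not
  special-cased.
* Whether the variance reported per figure in the source is whole-window
  or per-bin-averaged is ambiguous; both are available (`variance_pos`
  and per-bin `var` statistics) and are not interchangeable.
* Exact permutation Spearman p-values are limited to n ≤ 9 (9! ≈ 3.6e5
  permutations); beyond that the t approximation is used, which is
  slightly anti-conservative at small n.
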