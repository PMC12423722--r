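---
title: "Estimating brachial-ankle pulse wave velocity from wrist PPG and ECG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(wristpwv)
```

## The estimation problem

Brachial–ankle pulse wave velocity (baPWV, cm/s) indexes arterial
stiffness and is measured clinically with limb cuffs. Wrist wearables
record photoplethysmography (PPG) and single-lead ECG instead. The
estimation chain in this package turns a time-aligned wrist PPG/ECG
segment into a baPWV estimate in four stages: clean and segment the
signals, locate fiducial points, decompose each pulse into five Gaussian
component waves, compute a feature stack, and map features to baPWV with
a hierarchical classify-then-regress model.

Two properties of wrist PPG shape the design. First, the diastolic peak
and dicrotic notch frequently vanish, so features that depend on them
are recovered from the *decomposed* pulse (the synthesized diastolic
wave) rather than the raw contour. Second, single-channel timing alone
is weak, so the ECG R peak provides the timing anchor: the pulse arrival
time PAT = −n_R, the span from the R peak to the pulse foot.

## Preprocessing

**Baseline wander** is removed with a periodized orthogonal discrete
wavelet transform (sym8). At a sampling rate of 256 Hz, a level-9
decomposition puts the approximation band at [0, 0.25] Hz; zeroing the
approximation coefficients and reconstructing removes drift while
leaving the pulse band (0.5–10 Hz) essentially untouched. When the
record length is a multiple of 2^9 the transform is applied circularly
and the operation is an exact linear projection — applying it twice
changes nothing beyond floating-point rounding. Other lengths are
reflection-padded to the next multiple and cropped; the cost is a
boundary transient of roughly a second at each end, which the detection
stages ignore.

**Powerline interference** is suppressed with a second-order IIR notch
at 60 Hz, quality factor 30 (≈ 2 Hz rejection bandwidth), run
forward–backward for zero phase so fiducial timings are not delayed.
The quality factor is a design choice — only the notch frequency is
physically fixed.

**Normalization** maps the whole preprocessed segment affinely onto
[−1, +1] (not per cycle), so amplitudes are comparable across cycles of
one record while beat-to-beat amplitude variation is preserved.

**R peaks** are detected with an energy detector in the classical
bandpass → derivative → squaring → moving-window integration style
(5–25 Hz band, 150 ms window, threshold at 0.35 of the 99th-percentile
envelope, 200 ms refractory period), then refined to the local ECG
maximum. **Pulse onsets (valleys)** are found in two stages: systolic
upstrokes are located on a 15 Hz zero-phase low-passed copy, then each
onset is the nearest local minimum left of its upstroke on an 8 Hz
smoothing, refined within ±5 samples on a 12 Hz smoothing. The two-stage
scheme balances noise robustness (heavy smoothing) against the bias a
heavy smoother introduces at the asymmetric pulse foot; on noiseless
synthetic records detection is within ±2 samples of the constructed
onsets for every beat, which the test suite asserts.

**Cycle screening.** Cycles are valley-to-valley; each is paired with
the latest R peak at most 0.6 s before its onset (unpaired cycles are
flagged and dropped). The signal quality index computes the skewness and
coefficient of variation of the PPG cycle lengths and ECG RR intervals;
a record whose statistics exceed |skewness| ≤ 1.0 or CV ≤ 0.2 (defaults,
configurable — no published values exist for these thresholds) has its
cycles excluded. Both statistics use the population (N) denominator.
With one-minute records (40–70 beats) the sample skewness of cycle
lengths is itself noisy, so occasional rejections of clean records are
expected and are simply logged.

## Fiducial points

Landmark scans run on a 15 Hz zero-phase smoothed copy of the cycle
(amplitudes are read from the raw samples at the found positions). The
systolic peak is the first prominent maximum (≥ 50% of the cycle range).
The notch is the deepest point of the post-systolic basin — the global
minimum over the 60% of the cycle after the peak — rather than the first
local minimum, because the wrist notch is a shallow plateau on which a
first-local-minimum rule latches onto noise wiggles; a minimum sitting
at the search edge means the decay is monotone and the notch is reported
missing. The diastolic peak must rise at least 0.5% of the cycle range
above the notch, otherwise it is reported missing (the vanishing-peak
case). The maximal-slope point is the first local maximum of the first
derivative and must precede the systolic peak.

On the second derivative (SDPPG), points a–d are the first
maximum/minimum/maximum/minimum of the systolic region ([0, n_notch], or
[0, 0.4·M] when the notch is missing) after light 3-sample smoothing;
ties break toward the earliest index. Point e — the maximum "around the
systole/diastole boundary" — is searched in a ±10%·M window around the
notch estimate, strictly after the last resolved systolic point, and
point f is the first minimum after e. Because the boundary region
carries very little curvature, e and f are scanned on a 5 Hz zero-phase
low-passed second derivative; the second difference amplifies broadband
noise by far more than the boundary curvature amplitude, and without
this the a–f weighting window (and with it the decomposition) is
unstable under even 1% measurement noise. Cycles where a or b cannot be
resolved are unusable for SDPPG features.

## Weighted pulse decomposition

Each accepted cycle s(n), n = 0..M−1, is modeled as
G(n|Θ) = Σᵢ₌₁⁵ αᵢ·exp(−(n−βᵢ)²/(2γᵢ²)) with Θ the 15 component
parameters (amplitude, position, width — sample units). The fit
minimizes the weighted mean of squared residuals

> (1/M) · Σₙ w(n) · (s(n) − G(n|Θ))²,  w(n) = ω on [n_a, n_f], 1 elsewhere,

with ω = 80, subject to box bounds: α ∈ [0, 1.5·max(s)], β in ordered
fifths of [0, M) each extended by M/6 (so component order is kept by the
boxes alone and the solver stays a plain bounded minimization),
γ ∈ [1, M/4] samples. Normalized cycles are shifted by their minimum
before fitting (component waves are non-negative); the offset is
restored afterwards. When no a/f window is available the weight window
falls back to the whole cycle, which is recorded on the result.

The solver is projected quasi-Newton (`optim` L-BFGS-B) with the
analytic gradient, tight tolerances (factr = 10, up to 2000 iterations),
followed by an unbounded Levenberg–Marquardt polish whenever the
solution is interior — the quasi-Newton step crawls in the flat tail of
the Gaussian least-squares surface where LM converges quadratically.
Because the mixture surface is multi-modal (narrow-width and wide-width
basins compete, and G3/G4 can trade roles), the fit runs from a small
deterministic start grid — the fifth-midpoint default, a
narrow/high-amplitude and a wide/low-amplitude variant, plus one start
anchored on the located notch and diastolic peak when available — and
keeps the lowest objective. There is no randomness in the solver; a
given cycle, configuration and start always reproduce the same fit.
With an explicit initialization (as in the recovery tests) that start is
simply prepended to the grid.

The decomposition quality gate (WPD-SQI) is the unweighted
reconstruction MSE; fits above 2×10⁻³ are discarded (the threshold is
an exclusion rule on "strictly greater", so a fit at exactly 2×10⁻³
passes). Forward, systolic and diastolic waves are G1+G2, G1+G2+G3 and
G4+G5; their argmax positions p_f, p_s, p_d define SI = n_pd − n_ps. A
diastolic wave below 10⁻⁶ peak amplitude has no defined p_d and SI is
missing for that cycle.

## Features and aggregation

All interval features are stored in samples with the sampling interval
carried alongside (every interval in the method is an index difference;
seconds are a view). The named features: P2O = M − n_sys; landmark
positions/amplitudes; SDPPG amplitudes A_a²..A_f²; the ageing index
(A_b−A_c−A_d−A_e)/A_a and its reduced variant (A_b−A_c−A_d)/A_a
(denominators smaller than 10⁻⁹ make the feature missing); the
component parameters and SI, β₃−n_pf, β₄−n_pf; PAT = −n_R, PAT²,
Height²/PAT², and R-to-{max-slope, p_s, β₂} spans; and the
anthropometric block with La = 0.8219·H + 12.328,
Lb = 0.2195·H − 2.073 (cm, H validated to [100, 220] cm), their
difference, age and age². Ratio combination forms u/v over all ordered
feature pairs by default (a pair specification can restrict it), and a
missing or near-zero denominator yields a missing combined feature.
When the raw diastolic timing is missing but the decomposition passed
the gate, the synthesized diastolic-wave timing stands in, with the
provenance recorded as WPD-derived.

Aggregation is median-over-cycles within a sequence (robust to a
minority of corrupted cycles) and mean-over-sequence-medians within a
measurement; a feature missing in every sequence stays missing.

## Estimation models

The multivariable baselines are ordinary least squares of PWV on age
plus either the Fridericia-corrected stiffness index SI/M^(1/3) or the
pulse-length-normalized P2O/M.

The hierarchical model routes each measurement with a random-forest
classifier (binary label PWV < τ, τ = 1600 cm/s; 100 trees, depth 20,
minimum node size to split 3) and estimates with the routed submodel: an
XGBoost regressor trained on PWV ≤ τ + W/2 (low) or PWV ≥ τ − W/2
(high), where W is the overlapping zone (default 400 cm/s; 0–600
studied). Submodel defaults are 200 estimators, column subsampling 0.7,
minimum loss reduction 0, learning rate 0.1, depth 5 for the low
submodel and 3 for the high one. The overlap exists because
classification is unreliable exactly where the subdivisions meet: a
misrouted measurement near the boundary still falls inside the receiving
submodel's training range. Routing is a hard majority vote;
probability-weighted blending is available behind a non-default flag.
The general comparison model is a single XGBoost regressor with the same
defaults (depth 3).

Training hygiene: all splits are participant-disjoint and asserted on
every fit path; training sets are oversampled by duplication (fixed
seed, duplicates tagged) until every non-empty 100 cm/s PWV bin matches
the largest; hyperparameters can be chosen by leave-one-participant-out
validation over a grid, removing *all* of a held-out participant's
measurements from fitting, with ties preferring fewer trees and then
shallower depth.

## Evaluation

With e_j = measured − estimated: MAE = mean|e|, ME = mean e (positive
means underestimation), SD with the N−1 denominator, RMSE = √mean e².
These satisfy RMSE² = ME² + SD²·(N−1)/N, which the tests verify to
10⁻⁹. Correlation is Pearson with the two-sided t-based p-value
(Spearman behind a flag). Because participants contribute unequal
numbers of measurements, all reports are emitted at both round level and
participant level (pairs averaged per participant first). Bland–Altman
output uses difference = reference − estimate, bias = ME and limits
bias ± 1.96·SD.

## The synthetic-data module

No dataset is distributed with this problem, so the generators are
first-class, tested code and define the study conditions.

**Signal level.** A record is a concatenation of per-beat five-Gaussian
pulses. The default wrist template (fractions of the cycle length M)
is α = (0.85, 0.50, 0.30, 0.08, 0.16), β = (0.11, 0.19, 0.30, 0.48,
0.74)·M, γ = (0.040, 0.055, 0.075, 0.085, 0.140)·M: a dominant
forward/systolic complex, a shallow notch and a broad low diastolic wave
whose tail meets the next foot near-continuously. G4 is kept clearly
subordinate to G5 so the planted diastolic wave has a single unambiguous
peak — with near-equal humps the argmax defining SI is a knife-edge tie
and SI would not be a well-defined planted quantity. Per-beat morphology
jitter is 1% (resting, seated subjects over one minute; larger jitter
moves the true signal minimum itself away from the constructed onset,
confounding detector evaluation), heart-rate variability 1%, heart rate
72 bpm, PAT 70 samples (0.27 s). The ECG carries a narrow R spike and a
broader T bump per beat. Baseline wander (0.3 amplitude at 0.2 Hz),
60 Hz interference (0.05) and white noise (SD 0.01) are added; the
record lead-in holds the tail of a phantom beat so the record starts
mid-cycle like any real excerpt. Everything is a pure function of the
configuration and seed.

**Cohort level.** The signal-level cohort assigns each participant a
base PWV and maps PWV to morphology (shorter PAT, earlier and larger
diastolic wave at higher PWV) so that downstream recovery is possible.
The feature-level cohort — used for the model-comparison experiments,
where thousands of signal decompositions would dominate runtime without
adding information — draws 50 participants × 3 measurements with PWV
uniform on [1000, 2300] cm/s and builds features with an explicit regime
structure at τ = 1600: PAT shortens with PWV and saturates above the
boundary (slope −0.060 below, −0.018 above, noise SD 6 samples — the
noisy regime separator); SI and P2O relate to PWV with opposite slopes
on the two sides, flat within ±200 cm/s of the boundary, so their value
alone does not identify the regime and a model must resolve the regime
before using them — precisely the structure a classify-then-regress
model exploits — while the flat band keeps rows near the boundary
feature-interchangeable, so overlap-zone training imports no
contradictory labels; the ageing index is informative in the high range
only; age is a weak global trend; four pure-noise features are
appended. These choices were fixed during a design phase on separate
seed batches and are not revisited by the tests.

**What passing tests do and do not show.** The generators emulate
quasi-periodic morphology, additive disturbances and planted
feature–PWV structure. They do not model motion artifacts, arrhythmia,
sensor contact loss, or real physiologic coupling between timing and
stiffness; recovery and model-ordering results on these cohorts
demonstrate that the implementation is faithful and that the
hierarchical design behaves as intended under its assumptions — not
that the same margins would be obtained on clinical data.

## Numerical choices and degenerate inputs

Solver tolerance 10⁻¹⁰ (ftol/ptol for the polish), maximum 2000
iterations; extremum ties break earliest; flat cycles, constant signals,
empty feature sets, rank-deficient designs, out-of-range heights and
splits with overlapping participants all raise errors rather than
propagating silently. Cycle-relative positions are 0-based offsets from
the pulse onset (so n_R < 0); absolute indices follow R's 1-based
convention.

## Problem sizes

The test suite and acceptance script use: 100 random in-bounds pulses
(M = 200) for decomposition recovery; 60-beat records (5 replicates) for
detection rates; 20-seed model comparisons on 150-measurement cohorts
with 60-measurement boundary-confined test cohorts drawn on
[1400, 1800] cm/s; and an end-to-end signal-level run of 10 participants
× 2 rounds × 12 beats. These sizes keep a full run in minutes on one
core while leaving every comparison statistically interpretable.

## Known limitations

* The five-Gaussian split of a pulse is weakly identified in the
  diastolic region at realistic noise; SI inherits a few samples of
  variability (the deterministic multi-start and the low-passed boundary
  window reduce, but cannot eliminate, this).
* Foot localization under broadband noise is limited by the near-flat
  Gaussian tail at the pulse foot; at 20 dB SNR the valley hit rate
  within ±2 samples is below the R-peak rate, and the acceptance script
  reports both.
* The full published feature tables are not reproduced here; the catalog
  pins the features named in the method text and exposes a registry for
  extensions.
* Sex-specific modeling is a training-configuration convention (fit the
  same pipeline per subgroup), not a code fork.
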