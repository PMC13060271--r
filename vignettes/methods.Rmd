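---
title: "Models, statistics and design choices in pupilperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, statistics and design choices in pupilperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pupilperm implements the computational analysis of an interrupted,
reverberant auditory spatial-attention pupillometry paradigm. This vignette
documents the underlying models and every place where the design was
genuinely open — what was chosen, why, and what a passing test does and
does not establish.

## 1. The paradigm and its parameters

A trial is: a spatialized cue syllable (450 ms), then two interleaved
4-syllable streams (450 ms syllables, 150 ms gaps, so a 600 ms
within-stream onset asynchrony), the leading stream starting 500 ms after
the cue ends and the lagging stream 300 ms later — the merged mixture is
isochronous at 300 ms. On interrupted trials a 250 ms novel sound starts
125 ms before the 2nd target-syllable onset. 160 trials are split into 8
blocks of 20; in the primary blocking mode the room (anechoic vs
reverberant) is constant within a block and alternates across blocks, with
interruption and target side exactly counterbalanced within each block; the
variant mode blocks by interruption and intermingles rooms. All of these
are fields of `design_config()` with those values as defaults.

Time zero is **cue onset** (the epoching reference). The schedule stores
the cue duration (one syllable, 450 ms, since the cue is itself a
syllable), so quantities stated relative to cue *end* are recoverable by
subtraction; tests verify the canonical arithmetic (target onsets 0.5,
1.1, 1.7, 2.3 s after cue end; interrupter at 0.975 s after cue end).

With 20 trials per block the three binary within-block factors cannot all
be jointly crossed (20 is not divisible by 8): interruption × target side
are fully crossed and target-leading is balanced marginally, which
reproduces the stated per-block counts exactly.

**Power analysis.** `required_sample_size()` solves the exact
noncentral-*t* power equation for a two-tailed paired *t* test and rounds
the continuous solution to the nearest integer. At d = 0.37, α = 0.05,
power = 0.8 the continuous solution is 59.28, giving 59 — note that the
integer 59 has power 0.7988, so a "smallest n with power ≥ 0.8" convention
would give 60 instead; the nearest-integer convention is the one this
paradigm's published planning used and is the package's contract.

## 2. The synthetic-data generator

The source study deposits no raw data, so all downstream stages are
exercised on synthetic cohorts. The generative pupil model is the
package's own and makes three standard assumptions:

1. **Additivity**: the trace is a subject tonic level plus one kernel per
   stimulus event plus noise. Each syllable of *both* streams, the cue,
   and the interrupter evoke a kernel scaled by a class- and
   room-dependent amplitude.
2. **Kernel form**: the unit-peak Erlang-style response
   h(t) = (t/t_max)^n · exp(n(1 − t/t_max)) with n = 10.1 and
   t_max = 0.93 s — the conventional constants of the pupil-response
   literature, stated as defaults, not facts.
3. **Noise**: stationary AR(1) per sample plus Poisson-arriving blink
   gaps (gamma-distributed durations, shape 4) reported as missing
   samples, the way an eye tracker reports closures. Blinks are gaps, not
   artifact waveforms.

Default amplitudes (arbitrary units on a ~4000-unit tonic level) encode
the phenomenon the pipeline must recover: syllable responses are
attenuated by reverberation (50 vs 30) while interrupter responses barely
are (160 vs 150). Inter-trial spacing defaults to 8 s cue-to-cue so the
[−1, 7] s epochs tile exactly without overlap; shorter spacings error.

The AR(1) coefficient is *per sample*: when the tests run the generator at
50–60 Hz instead of the 1000 Hz hardware rate (purely for runtime — the
generator is rate-agnostic), the default 0.995 at 1000 Hz is rescaled as
0.995^20 ≈ 0.90 to preserve the noise bandwidth.

The behavioral generator draws each position correct with probability
base(position) − interruption penalty(position) − reverberation penalty,
clipped to [1/3, 1]; wrong answers are uniform over the two remaining
syllables. Defaults: base 0.85/0.70/0.65/0.75 (primacy and recency),
interruption penalties 0.03/0.12/0.07/0.04 (maximal right after the
interrupter), reverberation penalty 0.07 — magnitudes in the ≈5–10-point
range the paradigm reports qualitatively.

**What a green test establishes**: that the pipeline recovers effects
*of this additive, stationary form*. Real pupil data have luminance
responses, gaze-position artifacts, slow drifts and non-stationary blink
behavior that the generator deliberately omits; nothing here validates
robustness to those.

## 3. Preprocessing choices

- **Blink definition**: a maximal run of tracker-flagged invalid samples;
  no velocity-based detection.
- **Interpolation**: pads of 50 ms before / 150 ms after each run;
  overlapping padded windows are *merged before* interpolating (the
  alternative — interpolate sequentially — is path-dependent). Edge
  blinks hold the nearest valid value, since a line needs two anchors.
- **Filter**: 4th-order Butterworth, 10 Hz, applied forward-backward
  (zero phase). No signal-processing package ships with the target
  environment, so the bilinear-transform design and the
  odd-extension filtfilt are implemented in `R/filters.R`; the
  coefficients match the reference scipy implementation to machine
  precision and the tests pin the two-pass gain to the analytic
  magnitude response (1/(1+(f/10)^8) at f = 20 Hz ≈ 0.0039).
- **Epochs**: [−1, 7) s, half-open on the right; baselines over
  [−0.5, 0) — the sample at cue onset belongs to the stimulus.
- **Tonic statistics**: mean and *n−1* SD of per-trial baselines (the
  estimator is stated here because the source is silent). Tonic
  comparisons use raw units.
- **Phasic traces**: baseline-subtract per trial, average within
  condition, then divide by the tonic SD (z-score mode). Averaging
  precedes scaling deliberately. Alternative modes (`subtract_only`,
  `proportional`) are provided for robustness checks; z-scores are
  invariant to positive affine transforms of the raw units, a property
  the suite tests.
- **Exclusion**: whole-recording missing fraction, computed before
  interpolation, strictly greater than 50%.

## 4. Permutation statistics

**Cluster test.** Pointwise paired *t*; two-sided cluster-forming
threshold at the df = n−1 critical value; maximal contiguous
sign-constant supra-threshold runs; statistic = T-sum. The null flips
each subject's whole difference waveform (never individual time points)
and records the **maximum |T-sum|** per permutation — the standard
family-wise construction. The aggregation was an open question (the
procedure's description doesn't pin it); max-cluster is the default and a
`null = "pooled"` switch provides the more liberal pooled-null variant
for sensitivity analysis. Significance: observed |T-sum| strictly above
the null's 95th percentile; per-cluster p uses the inclusive ≥ rule so p
is never 0, and the observed statistic is not appended to the null.

**Scalar tests.** Peak latency = time of the maximum (earliest tie wins —
a deterministic convention); peak amplitude = mean over ±50 ms around it,
truncated at epoch edges; the search window defaults to the post-cue
epoch (0–7 s), configurable, since the baseline period should not host a
"peak". Main effects flip per-subject difference scores; the interaction
flips the difference-of-differences. For n ≤ 16 (scalar) or n ≤ 12
(cluster) the 2^n patterns are enumerated exhaustively, making p exact,
seed-free, and equal to hand-computable values (ten identical differences
→ p = 2/1024). The Shapiro–Wilk check is a reported *gate*, not a branch:
the inferential path is always nonparametric.

**Calibration.** The suite verifies family-wise error of the cluster test
and type-I error of the scalar test at ≈0.05 within 3 binomial SE over
500 null simulations, and Monte-Carlo/exhaustive agreement at Kolmogorov
distance < 0.02.

## 5. Room acoustics

Impulse responses come from spectral division of a recorded sweep by the
reference sweep with Tikhonov regularization ε = 10⁻⁸ × max|S|²
(configurable) to bound out-of-band bins. RT60 uses Schroeder backward
integration with a −5 to −25 dB fit range (T20 × 3 extrapolation — the
common standard, configurable; the method description pins only the
backward integration itself). The closed form for an exponential energy
decay exp(−t/τ) is RT60 = ln(10⁶)·τ ≈ 13.82τ, which the tests recover
within 5% across τ ∈ {0.05, 0.1, 0.2, 0.3} s. Pseudo-anechoic truncation
detects the direct-path onset at 10% of the absolute peak and keeps a
configurable window (no default is asserted as "the measured one" — the
original measurement's window length is unstated). The physical KEMAR
measurements themselves (classroom RT60 = 743 ms, concert hall 1.919 s)
are out of scope: they require the physical recordings.

## 6. Numerical and engineering notes

- All randomness flows from explicit integer seeds; cohort helpers derive
  per-subject seeds from a root seed below 2^31.
- Permutation sign matrices are applied as one matrix product; the
  per-column sum of squares is flip-invariant, so the permuted *t* traces
  need only the flipped means — this is what makes 500-simulation
  calibration runs affordable in pure R.
- The repeated-measures ANOVA is computed by `stats::aov` with an
  `Error(subject/(A*B*C))` stratification (no sphericity correction,
  plain df, as is conventional for this paradigm's reporting); the test
  suite checks it against an independent brute-force sums-of-squares
  oracle. Heavy suites scale the cohort (fewer subjects/trials, 50–60 Hz
  sampling) to stay inside runtime budgets; generating effect sizes,
  thresholds and tolerances are never adjusted.
- Zero-variance time points get t = 0 (conservative) with a warning;
  all-zero difference vectors get p = 1 by convention.

## 7. Known limitations

- The generator's additivity means saturation or refractoriness of
  successive pupil responses is not modeled.
- `rm_anova()` requires a complete balanced within-subject design; there
  is no mixed-model fallback for missing cells (trial-level GLMMs are
  explicitly out of scope).
- WAV I/O covers mono 16-bit PCM only.
- The cluster test assumes exchangeability under sign flips (symmetric
  paired null); heavy-tailed asymmetric nulls can miscalibrate it.
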