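# pupilperm

Analysis pipeline for **interrupted, reverberant auditory spatial-attention
pupillometry experiments**. In this paradigm a listener attends one of two
temporally interleaved syllable streams (one per hemifield) rendered either
pseudo-anechoically or with reverberation; on half the trials a sudden,
novel "interrupter" sound intrudes just before the 2nd target syllable. The
dependent measures are serial recall of the four target syllables and the
pupil dilation time course, whose tonic (pre-trial baseline) and phasic
(event-evoked) components index sustained and transient listening effort.

The package implements every stage of that analysis as reusable, tested
code, driven by a synthetic-data generator so the whole pipeline can be
exercised without any proprietary recordings:

- **Trial design & power** — counterbalanced trial/block construction with
  the paradigm's timing arithmetic, and exact noncentral-*t* power analysis
  for the within-subject contrast
  (`design_config()`, `build_design()`, `build_schedule()`,
  `required_sample_size()`).
- **Synthetic data** — additive event-kernel pupil model
  (*h(t) = (t/t*<sub>max</sub>)<sup>n</sup> e<sup>n(1−t/t_max)</sup>*, AR(1)
  noise, Poisson blink gaps) and a serial-recall generator with
  primacy/recency structure, an interruption penalty maximal at syllable 2,
  and a reverberation penalty (`simulate_subject()`, `simulate_behavior()`,
  `simulate_cohort()`).
- **Pupil preprocessing** — blink interpolation (50 ms pre / 150 ms post
  pads), 4th-order zero-phase Butterworth lowpass at 10 Hz, epoching
  [−1, 7] s around cue onset, [−0.5, 0) s baselines, tonic mean/SD, and
  z-scored / subtraction / proportional phasic traces
  (`interpolate_blinks()`, `lowpass()`, `epoch_series()`,
  `baseline_stats()`, `phasic()`).
- **Behavioral statistics** — strict positional serial-recall scoring,
  subject × room × interruption × position accuracy tables, the
  interruption effect, a 2 × 2 × 4 repeated-measures ANOVA, and
  Bonferroni-corrected paired post-hocs (`score_recall()`,
  `accuracy_table()`, `interruption_effect()`, `rm_anova()`,
  `posthoc_paired()`).
- **Time-course statistics** — paired cluster-based sign-flip permutation
  test with the max-|T-sum| family-wise null (exhaustive 2^n enumeration
  for n ≤ 12) (`cluster_permutation_test()`).
- **Peak statistics** — peak latency/amplitude (±50 ms window), a
  Shapiro–Wilk normality gate, and sign-flip permutation tests for main
  effects and the difference-of-differences interaction
  (`peak_latency()`, `peak_amplitude()`, `signflip_mean_test()`,
  `interaction_signflip_test()`).
- **Room acoustics** — sweep deconvolution with Tikhonov regularization,
  Schroeder backward-integration RT60, and direct-path (pseudo-anechoic)
  windowing (`deconvolve_sweep()`, `schroeder_rt60()`,
  `window_direct_path()`).
- **Orchestration** — `run_simulate()` / `run_analyze()` plus a CLI at
  `inst/cli/pupilperm` (`simulate`, `analyze`, `acoustics` subcommands).

## The core statistic

For each room, interrupted vs uninterrupted phasic traces are compared with
a paired cluster-based permutation test: pointwise paired *t* values are
thresholded at the two-sided *p* = 0.05 critical value (df = n−1), maximal
sign-constant supra-threshold runs form clusters scored by their **T-sum**
(Σt within the run), and the null distribution of the maximum |T-sum| is
built by randomly sign-flipping each subject's whole difference waveform
(10,000 permutations by default). A cluster is significant when its |T-sum|
exceeds the null's 95th percentile. Scalar peak measures use the same
sign-flip logic on per-subject difference scores, with exhaustive 2^n
enumeration for small cohorts so p-values are exact.

## Worked example

```r
library(pupilperm)

required_sample_size(power_spec(effect_size_d = 0.37, alpha = 0.05, power = 0.8))
#> [1] 59

pp <- pupil_gen_params(sampling_rate = 50, noise_ar1 = 0.995^20, seed = 1)
rc <- run_config(n_subjects = 6, pupil = pp, n_permutations = 500, seed = 1)
cohort <- simulate_cohort(6, rc$design, pp, rc$behavior, seed = 1)
pre <- lapply(cohort, function(s) preprocess_subject(s$series, s$events, rc))
beh <- do.call(rbind, lapply(names(cohort), function(s)
  transform(cohort[[s]]$behavior, subject = s)))
des <- do.call(rbind, lapply(names(cohort), function(s)
  transform(cohort[[s]]$design, subject = s)))
res <- analyze_cohort(pre, beh, des, rc)

res$effect_tests$amplitude$interruption[c("observed", "p")]
#> $observed
#> [1] 3.401337
#>
#> $p
#> [1] 0.03125
```

The observed value is the mean within-subject difference in peak phasic
amplitude (z-units), interrupted minus uninterrupted: interrupted trials
dilate more, and with n = 6 the exhaustive sign-flip p bottoms out at
2/2^6 = 0.03125 (all six subjects go the same way). The behavioral
interruption effect peaks at syllable position 2, where the generator
places its largest penalty:

```r
round(res$behavior$effect_by_position, 3)
#> [1] -0.006  0.090  0.077  0.027
```

(positions 1–4; at n = 6 the profile is noisy but already peaks at
position 2 — the generator's penalties are 0.03/0.12/0.07/0.04).

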