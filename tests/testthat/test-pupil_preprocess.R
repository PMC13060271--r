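make_series <- function(pupil, valid = rep(TRUE, length(pupil)), fs = 100) {
  sample_series(time = (seq_along(pupil) - 1) / fs, pupil = pupil,
                valid = valid, sampling_rate = fs)
}

test_that("find_invalid_runs enumerates maximal runs (0-based half-open)", {
  s <- make_series(rep(1, 500))
  expect_equal(nrow(find_invalid_runs(s)), 0)
  v <- rep(TRUE, 500)
  v[101:200] <- FALSE          # 0-based samples 100..199
  s <- make_series(rep(1, 500), v)
  expect_equal(find_invalid_runs(s), data.frame(start = 100, end = 200))
  # two runs separated by one valid sample stay separate
  v2 <- rep(TRUE, 50)
  v2[10:14] <- FALSE; v2[16:20] <- FALSE
  runs <- find_invalid_runs(make_series(rep(1, 50), v2))
  expect_equal(nrow(runs), 2)
  expect_equal(runs$start, c(9, 15))
  expect_equal(runs$end, c(14, 20))
})

test_that("blink interpolation is exact on linear signals", {
  fs <- 100
  x <- seq(0, 10, length.out = 1001)       # a perfect ramp
  v <- rep(TRUE, 1001)
  v[400:450] <- FALSE
  out <- interpolate_blinks(make_series(x, v, fs))
  expect_equal(out$pupil, x, tolerance = 1e-12)
  expect_true(all(out$valid))
  expect_equal(sum(out$was_missing), 51)
})

test_that("padded gap between two plateaus becomes the connecting line", {
  fs <- 1000
  x <- c(rep(4, 1000), rep(6, 1000))
  v <- rep(TRUE, 2000)
  v[1001:1100] <- FALSE   # 100 ms gap right at the step
  out <- interpolate_blinks(make_series(x, v, fs))
  # padded window: 50 ms before sample 1000 (0-based), 150 ms after 1100
  gap <- 951:1250                        # 1-based interior of padded span
  anchors <- c(950, 1251)
  expected <- approx(anchors, x[anchors], xout = gap)$y
  expect_equal(out$pupil[gap], expected, tolerance = 1e-12)
  expect_equal(out$pupil[1:949], x[1:949])
  expect_equal(out$pupil[1252:2000], x[1252:2000])
})

test_that("overlapping padded blinks merge into one span", {
  fs <- 1000
  x <- sin(seq(0, 4 * pi, length.out = 2000))
  v <- rep(TRUE, 2000)
  v[501:540] <- FALSE
  v[600:650] <- FALSE   # padded windows overlap (150 ms post + 50 ms pre)
  out <- interpolate_blinks(make_series(x, v, fs))
  # one straight line from the left anchor of blink 1 to the right anchor
  # of blink 2: values strictly between the anchors must be collinear
  span <- 452:799
  fit <- lm(out$pupil[span] ~ span)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("edge blinks hold the nearest valid value", {
  fs <- 100
  x <- c(rep(0, 20), seq(1, 10, length.out = 80))
  v <- rep(TRUE, 100); v[1:10] <- FALSE
  out <- interpolate_blinks(make_series(x, v, fs))
  # padded window reaches sample 25 (150 ms post-pad); held at anchor value
  expect_equal(unique(out$pupil[1:25]), x[26])
  expect_error(interpolate_blinks(make_series(rep(1, 50), rep(FALSE, 50))),
               "fully invalid")
})

test_that("interpolating a gap-free series is the identity", {
  x <- rnorm(300)
  out <- interpolate_blinks(make_series(x))
  expect_equal(out$pupil, x)
})

test_that("zero-phase filter: DC gain, stop-band attenuation, symmetry", {
  fs <- 1000
  s <- make_series(rep(5, 2000), fs = fs)
  out <- lowpass(s)
  expect_lt(max(abs(out$pupil - 5)), 1e-6)
  # 20 Hz sinusoid: two-pass gain = squared Butterworth magnitude
  t <- (0:9999) / fs
  sine <- make_series(sin(2 * pi * 20 * t), fs = fs)
  y <- lowpass(sine)$pupil[3000:7000]
  gain <- (max(y) - min(y)) / 2
  expect_equal(gain, butterworth_gain(20, 10, 4)^2, tolerance = 0.02)
  # symmetric pulse keeps its peak position (no phase distortion)
  tri <- c(rep(0, 500), seq(0, 1, length.out = 250),
           seq(1, 0, length.out = 250), rep(0, 500))
  ytri <- lowpass(make_series(tri, fs = fs))$pupil
  expect_lt(abs(which.max(ytri) - which.max(tri)), 3)
  expect_error(lowpass(make_series(rnorm(100), fs = 15), cutoff = 10),
               "Nyquist")
})

test_that("epoching cuts the right half-open windows", {
  fs <- 100
  n <- 3000
  x <- rep(1, n)
  pulse_at <- function(t0) round(t0 * fs) + 1
  x[pulse_at(12)] <- 9   # pulse 2 s after the cue at t = 10
  x[pulse_at(22)] <- 9   # pulse 2 s after the cue at t = 20
  s <- make_series(x, fs = fs)
  ep <- epoch_series(s, cue_onsets = c(10, 20), window = c(-1, 7))
  expect_equal(dim(ep$epochs), c(2, 800))
  expect_equal(ep$epoch_time[1], -1)
  expect_equal(ep$epoch_time[800], 7 - 1 / fs)  # half-open right edge
  for (i in 1:2)
    expect_equal(ep$epoch_time[which.max(ep$epochs[i, ])], 2)
  expect_error(epoch_series(s, cue_onsets = 29, window = c(-1, 7)),
               "bounds")
})

test_that("exclusion threshold is a strict inequality at 50%", {
  mf <- c(a = 0, b = 0.51, c = 0.5)
  qc <- exclude_high_missing(mf)
  expect_equal(qc$excluded, c(FALSE, TRUE, FALSE))
  # brute-force check on simulated subjects with very different blink loads
  cfg <- tiny_config(seed = 13)
  d <- build_design(cfg)
  rates <- c(0.05, 0.8)
  fracs <- vapply(seq_along(rates), function(i) {
    pp <- fast_pupil_params(blink_rate = rates[i],
                            blink_duration_mean = 1.5, seed = 100 + i)
    sim <- simulate_subject(d, cfg, pp)
    mean(!sim$series$valid)
  }, numeric(1))
  qc2 <- exclude_high_missing(setNames(fracs, c("lo", "hi")))
  expect_equal(qc2$excluded, fracs > 0.5)
  expect_true(qc2$excluded[2])
})

test_that("baseline statistics match hand arithmetic", {
  fs <- 10
  ep <- list(epochs = rbind(c(rep(4, 10), rep(0, 70)),
                            c(rep(6, 10), rep(0, 70))),
             epoch_time = seq(-1, 7 - 1 / fs, by = 1 / fs))
  class(ep) <- "epoch_set"
  bl <- baseline_stats(ep, c(-0.5, 0))
  expect_equal(bl$per_trial_baseline, c(4, 6))
  expect_equal(bl$tonic_mean, 5)
  expect_equal(bl$tonic_sd, sd(c(4, 6)))   # n-1 estimator
  # shift equivariance
  ep2 <- ep; ep2$epochs <- ep$epochs + 3
  bl2 <- baseline_stats(ep2, c(-0.5, 0))
  expect_equal(bl2$tonic_mean, 8)
  expect_equal(bl2$tonic_sd, bl$tonic_sd)
  expect_error(baseline_stats(ep, c(0.2, 0.2)), "empty")
})

test_that("phasic traces match a hand-computed z-score oracle", {
  # 3 trials x 5 samples; baseline window covers the first 2 samples
  ep <- list(epochs = rbind(c(1, 1, 3, 5, 1),
                            c(2, 2, 4, 8, 2),
                            c(3, 3, 3, 3, 3)),
             epoch_time = c(-0.4, -0.2, 0, 0.2, 0.4))
  class(ep) <- "epoch_set"
  bl <- baseline_stats(ep, c(-0.5, 0))
  expect_equal(bl$per_trial_baseline, c(1, 2, 3))
  ph <- phasic(ep, bl, mode = "zscore")$all
  corrected <- ep$epochs - c(1, 2, 3)
  expect_equal(ph$trace, colMeans(corrected) / sd(c(1, 2, 3)))
  expect_equal(ph$n_trials_averaged, 3)
  sub <- phasic(ep, bl, mode = "subtract_only")$all
  expect_equal(sub$trace, colMeans(corrected))
  prop <- phasic(ep, bl, mode = "proportional")$all
  expect_equal(prop$trace, colMeans(corrected / c(1, 2, 3)))
})

test_that("phasic modes have the stated invariances", {
  set.seed(1)
  ep <- list(epochs = matrix(rnorm(6 * 40, mean = 10), 6, 40),
             epoch_time = seq(-1, 7, length.out = 40))
  class(ep) <- "epoch_set"
  bl <- baseline_stats(ep, c(-0.5, 0))
  z0 <- phasic(ep, bl, "zscore")$all$trace
  s0 <- phasic(ep, bl, "subtract_only")$all$trace
  # positive affine transform of raw units
  a <- 3.7; b <- 42
  ep2 <- ep; ep2$epochs <- a * ep$epochs + b
  bl2 <- baseline_stats(ep2, c(-0.5, 0))
  expect_equal(phasic(ep2, bl2, "zscore")$all$trace, z0, tolerance = 1e-10)
  expect_equal(phasic(ep2, bl2, "subtract_only")$all$trace, a * s0,
               tolerance = 1e-10)
  # epochs identical to their baselines -> zero trace in all modes
  epc <- ep; epc$epochs <- matrix(rep(bl$per_trial_baseline, 40), 6, 40)
  blc <- baseline_stats(epc, c(-0.5, 0))
  expect_equal(max(abs(phasic(epc, blc, "subtract_only")$all$trace)), 0)
  expect_equal(max(abs(phasic(epc, blc, "proportional")$all$trace)), 0)
  expect_equal(max(abs(phasic(epc, blc, "zscore")$all$trace)), 0)
  # all-equal baselines degenerate the z-score denominator
  epd <- ep; epd$epochs <- matrix(5, 6, 40)
  bld <- baseline_stats(epd, c(-0.5, 0))
  expect_error(phasic(epd, bld, "zscore"), "degenerate")
})

test_that("filtering commutes with epoching away from edges", {
  fs <- 100
  set.seed(4)
  x <- cumsum(rnorm(4000)) / 10 + 100
  s <- make_series(x, fs = fs)
  filt_then_epoch <- epoch_series(lowpass(s), c(15, 25), c(-1, 7))
  sub <- epoch_series(s, c(15, 25), c(-5, 10))
  for (i in 1:2) {
    inner <- lowpass(make_series(sub$epochs[i, ], fs = fs))$pupil
    # compare on the [-1, 7) part, away from the sub-series edges
    sel <- sub$epoch_time >= -1 & sub$epoch_time < 7
    expect_equal(filt_then_epoch$epochs[i, ], inner[sel], tolerance = 1e-6)
  }
})

test_that("processing a clean synthetic subject recovers the kernel sum", {
  cfg <- tiny_config(seed = 21)
  d <- build_design(cfg)
  pp <- fast_pupil_params(noise_sd = 0, blink_rate = 0, tonic_sd = 0)
  sim <- simulate_subject(d, cfg, pp)
  clean <- interpolate_blinks(sim$series)
  filt <- lowpass(clean)
  ep <- epoch_series(filt, sim$events$cue_onset_s, c(-1, 7))
  # trial 1's epoch should equal tonic + its own kernel sum (events from
  # neighbouring trials have decayed); reconstruct directly
  k <- 1
  sched <- build_schedule(d[k, ], cfg)
  amp <- pp$amplitude
  syl <- amp[[paste0("syllable_", d$room[k])]]
  expected <- pp$tonic_mean + amp[["cue"]] * pupil_kernel(ep$epoch_time) +
    Reduce(`+`, lapply(sched$target_onsets, function(on)
      syl * pupil_kernel(ep$epoch_time - on))) +
    Reduce(`+`, lapply(sched$distractor_onsets, function(on)
      syl * pupil_kernel(ep$epoch_time - on))) +
    (if (d$interrupted[k])
       amp[[paste0("interrupter_", d$room[k])]] *
         pupil_kernel(ep$epoch_time - sched$interrupter_onset) else 0)
  # 10 Hz lowpass barely touches the ~1 Hz kernel; allow a small bound
  expect_lt(max(abs(ep$epochs[k, ] - expected)), 0.01 * max(expected))
})

test_that("sample series round-trips through CSV", {
  s <- make_series(rnorm(100), valid = rep(c(TRUE, FALSE), 50), fs = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_series(s, path)
  r <- read_sample_series(path)
  expect_equal(r$pupil, s$pupil)
  expect_equal(r$valid, s$valid)
  expect_equal(sampling_rate(r), 100, tolerance = 1e-6)
})
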