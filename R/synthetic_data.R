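#' Synthetic pupil generator parameters
#'
#' The generator is additive: a subject-specific tonic level, plus one
#' event-evoked kernel per stimulus event (cue, every syllable of both
#' streams, interrupter) scaled by a class- and room-specific amplitude,
#' plus stationary AR(1) measurement noise; blinks are Poisson-arriving
#' intervals of missing samples. Amplitudes are in the same arbitrary
#' units as the tonic level (EyeLink-style area units). The kernel is the
#' unit-peak Erlang-style form h(t) = (t/t_max)^n exp(n (1 - t/t_max))
#' with the conventional pupil-response constants n = 10.1,
#' t_max = 0.93 s.
#'
#' The default room-dependence encodes the phenomenon the analysis is
#' meant to recover: reverberation attenuates syllable-evoked dilations
#' but hardly affects interrupter-evoked ones.
#'
#' @param sampling_rate Samples per second (hardware default 1000; tests
#'   may lower it for speed — the generator is rate-agnostic).
#' @param tonic_mean,tonic_sd Between-subject distribution of the tonic
#'   pupil level, arbitrary units.
#' @param kernel_n,kernel_tmax Kernel shape and peak time (s).
#' @param amplitude Named vector with entries `cue`, `syllable_anechoic`,
#'   `syllable_reverberant`, `interrupter_anechoic`,
#'   `interrupter_reverberant` (pupil units, >= 0).
#' @param noise_sd Stationary SD of the AR(1) noise, pupil units.
#' @param noise_ar1 Lag-1 autocorrelation per sample, in [0, 1).
#' @param blink_rate Blink onsets per second.
#' @param blink_duration_mean Mean blink duration, seconds (gamma-shaped,
#'   shape 4).
#' @param iti Cue-to-cue interval, seconds; must be at least the epoch
#'   span (8 s for the default [-1, 7] s window) so epochs do not overlap.
#' @param seed Integer seed.
#' @return An object of class `pupil_gen_params`.
#' @export
pupil_gen_params <- function(sampling_rate = 1000,
                             tonic_mean = 4000, tonic_sd = 400,
                             kernel_n = 10.1, kernel_tmax = 0.93,
                             amplitude = c(cue = 80,
                                           syllable_anechoic = 50,
                                           syllable_reverberant = 30,
                                           interrupter_anechoic = 160,
                                           interrupter_reverberant = 150),
                             noise_sd = 50, noise_ar1 = 0.995,
                             blink_rate = 0.2, blink_duration_mean = 0.25,
                             iti = 8, seed = 1L) {
  need <- c("cue", "syllable_anechoic", "syllable_reverberant",
            "interrupter_anechoic", "interrupter_reverberant")
  if (!all(need %in% names(amplitude)))
    stop("amplitude must name: ", paste(need, collapse = ", "))
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  if (noise_ar1 < 0 || noise_ar1 >= 1) stop("noise_ar1 must be in [0, 1)")
  structure(list(sampling_rate = sampling_rate, tonic_mean = tonic_mean,
                 tonic_sd = tonic_sd, kernel_n = kernel_n,
                 kernel_tmax = kernel_tmax,
                 amplitude = amplitude[need], noise_sd = noise_sd,
                 noise_ar1 = noise_ar1, blink_rate = blink_rate,
                 blink_duration_mean = blink_duration_mean,
                 iti = iti, seed = as.integer(seed)),
            class = "pupil_gen_params")
}

#' Event-evoked pupil response kernel
#'
#' Unit-peak causal kernel h(t) = (t/t_max)^n exp(n (1 - t/t_max)):
#' h(0) = 0, h(t_max) = 1, h -> 0 as t grows. Negative times return 0.
#'
#' @param t Time since event onset, seconds (vectorized).
#' @param n Shape parameter (> 0).
#' @param t_max Peak time, seconds (> 0).
#' @return Kernel values in [0, 1].
#' @export
pupil_kernel <- function(t, n = 10.1, t_max = 0.93) {
  if (n <= 0 || t_max <= 0) stop("n and t_max must be > 0")
  out <- numeric(length(t))
  pos <- !is.na(t) & t > 0
  x <- t[pos] / t_max
  out[pos] <- exp(n * (log(x) + 1 - x))
  out[is.na(t)] <- NA_real_
  out
}

#' Simulate one subject's continuous pupil recording
#'
#' Lays the trials of `design` out at `params$iti` cue-to-cue spacing
#' (first cue 2 s into the recording), sums event kernels, adds AR(1)
#' noise, and marks Poisson-arriving blink intervals invalid (pupil
#' forced to 0 there, as an eye tracker reports dropouts).
#'
#' @param design Output of [build_design()].
#' @param config The matching [design_config()].
#' @param params A [pupil_gen_params()].
#' @return List: `series` (a [sample_series()]), `events` (data.frame
#'   `trial`, `cue_onset_s`, `room`, `interrupted`), `tonic` (the subject's
#'   generating tonic level).
#' @export
simulate_subject <- function(design, config, params) {
  stopifnot(inherits(params, "pupil_gen_params"))
  fs <- params$sampling_rate
  if (params$iti < 8)
    stop("overlapping epochs: iti shorter than the 8 s epoch span")
  n_trials <- nrow(design)
  cue_onsets <- 2 + params$iti * (seq_len(n_trials) - 1)
  total <- max(cue_onsets) + 7 + 1
  n <- as.integer(round(total * fs)) + 1L
  tt <- (seq_len(n) - 1) / fs

  set.seed(params$seed)
  tonic <- stats::rnorm(1, params$tonic_mean, params$tonic_sd)
  pupil <- rep(tonic, n)

  ksup_len <- as.integer(6 * fs)   # kernel support; < 1e-4 beyond 6 s
  add_event <- function(onset, amp) {
    if (amp == 0) return()
    i0 <- as.integer(ceiling(onset * fs)) + 1L  # first sample at/after onset
    idx <- i0:min(n, i0 + ksup_len - 1L)
    pupil[idx] <<- pupil[idx] +
      amp * pupil_kernel(tt[idx] - onset, params$kernel_n,
                         params$kernel_tmax)
  }
  amp <- params$amplitude
  for (i in seq_len(n_trials)) {
    tr <- design[i, ]
    sched <- build_schedule(tr, config)
    t0 <- cue_onsets[i]
    syl_amp <- amp[[paste0("syllable_", tr$room)]]
    add_event(t0, amp[["cue"]])
    for (on in sched$target_onsets) add_event(t0 + on, syl_amp)
    for (on in sched$distractor_onsets) add_event(t0 + on, syl_amp)
    if (isTRUE(tr$interrupted))
      add_event(t0 + sched$interrupter_onset,
                amp[[paste0("interrupter_", tr$room)]])
  }

  if (params$noise_sd > 0) {
    phi <- params$noise_ar1
    innov <- stats::rnorm(n, 0, params$noise_sd * sqrt(1 - phi^2))
    noise <- if (phi > 0)
      as.numeric(stats::filter(innov, phi, method = "recursive"))
    else innov
    pupil <- pupil + noise
  }

  valid <- rep(TRUE, n)
  if (params$blink_rate > 0) {
    n_blinks <- stats::rpois(1, params$blink_rate * total)
    if (n_blinks > 0) {
      onsets <- sort(stats::runif(n_blinks, 0, total))
      durs <- stats::rgamma(n_blinks, shape = 4,
                            scale = params$blink_duration_mean / 4)
      for (j in seq_len(n_blinks)) {
        i0 <- as.integer(round(onsets[j] * fs)) + 1L
        i1 <- min(n, i0 + as.integer(round(durs[j] * fs)))
        valid[i0:i1] <- FALSE
      }
      pupil[!valid] <- 0
    }
  }

  series <- sample_series(time = tt, pupil = pupil, valid = valid,
                          sampling_rate = fs)
  events <- data.frame(trial = design$trial, cue_onset_s = cue_onsets,
                       room = design$room, interrupted = design$interrupted,
                       stringsAsFactors = FALSE)
  list(series = series, events = events, tonic = tonic)
}

#' Synthetic serial-recall generator parameters
#'
#' Per-position accuracy with primacy/recency structure, an interruption
#' penalty maximal at the 2nd syllable (the one right after the
#' interrupter), and a reverberation penalty. Per-cell probabilities are
#' clipped to [1/3, 1] (chance on a 3-alternative set). Defaults give
#' roughly 65-85% accuracy with a ~12-point interruption cost at
#' position 2 and a 7-point reverberation cost.
#'
#' @param base_accuracy_by_position Per-position probability correct for
#'   uninterrupted anechoic trials.
#' @param interruption_penalty_by_position Per-position decrement applied
#'   on interrupted trials.
#' @param reverb_penalty Decrement applied on reverberant trials.
#' @param seed Integer seed.
#' @return An object of class `behavior_gen_params`.
#' @export
behavior_gen_params <- function(base_accuracy_by_position =
                                  c(0.85, 0.70, 0.65, 0.75),
                                interruption_penalty_by_position =
                                  c(0.03, 0.12, 0.07, 0.04),
                                reverb_penalty = 0.07,
                                seed = 1L) {
  if (length(base_accuracy_by_position) !=
      length(interruption_penalty_by_position))
    stop("penalty and base accuracy vectors must have equal length")
  structure(list(base_accuracy_by_position = base_accuracy_by_position,
                 interruption_penalty_by_position =
                   interruption_penalty_by_position,
                 reverb_penalty = reverb_penalty, seed = as.integer(seed)),
            class = "behavior_gen_params")
}

#' Simulate serial-recall responses for one subject
#'
#' Each position is recalled correctly with probability
#' p(position, interrupted, room); incorrect responses are drawn uniformly
#' from the two remaining syllables. Probabilities falling below chance
#' after penalties are clipped to 1/3 with a warning.
#'
#' @param design Output of [build_design()].
#' @param params A [behavior_gen_params()].
#' @return Data.frame: `trial`, `position` (1-based), `target`,
#'   `response`, `correct`.
#' @export
simulate_behavior <- function(design, params) {
  stopifnot(inherits(params, "behavior_gen_params"))
  set.seed(params$seed)
  k <- length(params$base_accuracy_by_position)
  rows <- vector("list", nrow(design))
  clipped <- FALSE
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    targets <- strsplit(tr$target_syllables, "-", fixed = TRUE)[[1]]
    if (length(targets) != k)
      stop("design has ", length(targets), " syllables but params cover ", k)
    p <- params$base_accuracy_by_position -
      (if (isTRUE(tr$interrupted))
         params$interruption_penalty_by_position else 0) -
      (if (tr$room == "reverberant") params$reverb_penalty else 0)
    if (any(p < 1 / 3)) clipped <- TRUE
    p <- pmin(1, pmax(1 / 3, p))
    ok <- stats::runif(k) < p
    resp <- targets
    for (j in which(!ok))
      resp[j] <- sample(setdiff(SYLLABLE_SET, targets[j]), 1)
    rows[[i]] <- data.frame(trial = tr$trial, position = seq_len(k),
                            target = targets, response = resp,
                            correct = as.integer(ok),
                            stringsAsFactors = FALSE)
  }
  if (clipped)
    warning("some cell probabilities fell below chance and were clipped to 1/3")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a multi-subject cohort
#'
#' Draws one design, one pupil recording and one behavioral response table
#' per subject, deriving per-subject seeds from a root seed.
#'
#' @param n_subjects Number of subjects.
#' @param config A [design_config()] (its seed is re-derived per subject).
#' @param pupil_params A [pupil_gen_params()] template.
#' @param behavior_params A [behavior_gen_params()] template, or NULL to
#'   skip behavior.
#' @param seed Root seed.
#' @return Named list (one element per subject) with `design`, `series`,
#'   `events`, `behavior`.
#' @export
simulate_cohort <- function(n_subjects, config = design_config(),
                            pupil_params = pupil_gen_params(),
                            behavior_params = behavior_gen_params(),
                            seed = 1L) {
  lapply(stats::setNames(seq_len(n_subjects),
                         sprintf("S%03d", seq_len(n_subjects))),
         function(s) {
    sseed <- (seed * 1009L + s * 7L) %% 2147483647L
    cfg <- config
    cfg$seed <- sseed
    des <- build_design(cfg)
    pp <- pupil_params
    pp$seed <- sseed + 1L
    sim <- simulate_subject(des, cfg, pp)
    beh <- NULL
    if (!is.null(behavior_params)) {
      bp <- behavior_params
      bp$seed <- sseed + 2L
      beh <- simulate_behavior(des, bp)
    }
    list(design = des, series = sim$series, events = sim$events,
         behavior = beh, tonic = sim$tonic)
  })
}
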