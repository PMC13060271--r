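#' Continuous pupil recording
#'
#' A uniformly sampled pupil trace with a per-sample validity flag
#' (invalid = blink / eye closure, i.e. missing data).
#'
#' @param time Sample times, seconds, uniform and strictly increasing.
#' @param pupil Pupil size, arbitrary units.
#' @param valid Logical per sample.
#' @param sampling_rate Hz.
#' @return Data.frame of class `sample_series` with columns `time`,
#'   `pupil`, `valid` and attribute `sampling_rate`.
#' @export
sample_series <- function(time, pupil, valid = rep(TRUE, length(time)),
                          sampling_rate) {
  n <- length(time)
  if (length(pupil) != n || length(valid) != n)
    stop("time, pupil and valid must have equal length")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (n > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (max(abs(dt - 1 / sampling_rate)) > 0.01 / sampling_rate)
      stop("time grid is not uniform at the stated sampling rate")
  }
  structure(data.frame(time = time, pupil = pupil, valid = as.logical(valid)),
            sampling_rate = sampling_rate,
            class = c("sample_series", "data.frame"))
}

#' Sampling rate accessor
#' @param series A [sample_series()].
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(series) attr(series, "sampling_rate")

#' Find maximal runs of invalid samples
#'
#' @param series A [sample_series()].
#' @return Data.frame with columns `start`, `end`: half-open 0-based
#'   sample-index intervals (so `start / fs` is the time of the first
#'   invalid sample). Empty when all samples are valid.
#' @export
find_invalid_runs <- function(series) {
  r <- rle(!series$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# merge overlapping/adjacent half-open intervals, given sorted starts
merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$start), ]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  res <- list()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e) {
      out_e <- max(out_e, iv$end[i])
    } else {
      res[[length(res) + 1]] <- c(out_s, out_e)
      out_s <- iv$start[i]; out_e <- iv$end[i]
    }
  }
  res[[length(res) + 1]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Linearly interpolate across blink gaps
#'
#' Each run of invalid samples is padded by `pre_pad` seconds before its
#' onset and `post_pad` seconds after its offset; overlapping padded
#' windows are merged, and every padded window is replaced by the straight
#' line between the valid samples at its boundaries. Blinks abutting the
#' recording edge are filled by holding the nearest valid value. All
#' samples are marked valid afterward; the pre-interpolation missingness
#' is preserved in a `was_missing` column for downstream QC and epoch
#' bookkeeping.
#'
#' @param series A [sample_series()].
#' @param pre_pad,post_pad Padding, seconds (defaults 50 ms / 150 ms).
#' @return A [sample_series()] with all samples valid and an added
#'   `was_missing` column.
#' @export
interpolate_blinks <- function(series, pre_pad = 0.05, post_pad = 0.15) {
  fs <- sampling_rate(series)
  n <- nrow(series)
  if (!any(series$valid)) stop("fully invalid series: nothing to anchor on")
  out <- series
  out$was_missing <- !series$valid
  runs <- find_invalid_runs(series)
  if (nrow(runs) > 0) {
    runs$start <- pmax(0L, runs$start - as.integer(round(pre_pad * fs)))
    runs$end <- pmin(n, runs$end + as.integer(round(post_pad * fs)))
    runs <- merge_intervals(runs)
    for (i in seq_len(nrow(runs))) {
      gap <- (runs$start[i] + 1L):runs$end[i]     # 1-based indices
      left <- runs$start[i]                        # 1-based anchor before gap
      right <- runs$end[i] + 1L                    # 1-based anchor after gap
      if (left >= 1 && right <= n) {
        out$pupil[gap] <- out$pupil[left] +
          (out$pupil[right] - out$pupil[left]) *
          (gap - left) / (right - left)
      } else if (left >= 1) {
        out$pupil[gap] <- out$pupil[left]
      } else if (right <= n) {
        out$pupil[gap] <- out$pupil[right]
      } else {
        stop("fully invalid series: nothing to anchor on")
      }
    }
  }
  out$valid <- TRUE
  out
}

#' Zero-phase Butterworth lowpass for a pupil series
#'
#' @param series A [sample_series()] with all samples valid (interpolate
#'   blinks first).
#' @param order Filter order (default 4).
#' @param cutoff Cutoff, Hz (default 10); must be below Nyquist.
#' @param zero_phase Apply forward-backward (default TRUE).
#' @return The filtered series.
#' @export
lowpass <- function(series, order = 4, cutoff = 10, zero_phase = TRUE) {
  fs <- sampling_rate(series)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (!all(series$valid))
    stop("series contains invalid samples; interpolate blinks first")
  co <- butter_lowpass(order, cutoff, fs)
  out <- series
  out$pupil <- if (zero_phase) filtfilt(co$b, co$a, series$pupil)
               else iir_filter(co$b, co$a, series$pupil)
  out
}

#' Epoch a series around cue onsets
#'
#' Cuts one row per trial over `window` (half-open at the right edge)
#' relative to each cue onset. The per-trial missing fraction is computed
#' from pre-interpolation validity (`was_missing` if present, else
#' `!valid`).
#'
#' @param series A [sample_series()].
#' @param cue_onsets Cue onset times, seconds.
#' @param window Epoch window relative to cue onset, seconds
#'   (default c(-1, 7)).
#' @param labels Optional data.frame of per-trial labels (e.g. `room`,
#'   `interrupted`), one row per cue.
#' @return An `epoch_set`: list with `epochs` (trials x time matrix),
#'   `epoch_time`, `trial_labels`, `missing_fraction`.
#' @export
epoch_series <- function(series, cue_onsets, window = c(-1, 7),
                         labels = NULL) {
  fs <- sampling_rate(series)
  n_samp <- as.integer(round(diff(window) * fs))
  epoch_time <- window[1] + (seq_len(n_samp) - 1) / fs
  t0 <- series$time[1]
  miss <- if ("was_missing" %in% names(series)) series$was_missing
          else !series$valid
  n <- nrow(series)
  epochs <- matrix(NA_real_, nrow = length(cue_onsets), ncol = n_samp)
  mfrac <- numeric(length(cue_onsets))
  for (i in seq_along(cue_onsets)) {
    i0 <- as.integer(round((cue_onsets[i] + window[1] - t0) * fs)) + 1L
    i1 <- i0 + n_samp - 1L
    if (i0 < 1 || i1 > n)
      stop("epoch window for trial ", i - 1, " exceeds recording bounds")
    epochs[i, ] <- series$pupil[i0:i1]
    mfrac[i] <- mean(miss[i0:i1])
  }
  if (!is.null(labels) && nrow(labels) != length(cue_onsets))
    stop("labels must have one row per cue onset")
  structure(list(epochs = epochs, epoch_time = epoch_time,
                 trial_labels = labels, missing_fraction = mfrac),
            class = "epoch_set")
}

#' Flag subjects with excessive missing data
#'
#' @param missing_fractions Named numeric vector: per-subject fraction of
#'   missing samples over the whole recording, computed before blink
#'   interpolation.
#' @param threshold Exclusion threshold; a subject is excluded when its
#'   fraction strictly exceeds this (default 0.5).
#' @return Data.frame `subject`, `missing_fraction`, `excluded`.
#' @export
exclude_high_missing <- function(missing_fractions, threshold = 0.5) {
  data.frame(subject = names(missing_fractions),
             missing_fraction = as.numeric(missing_fractions),
             excluded = as.numeric(missing_fractions) > threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-trial baselines and tonic statistics
#'
#' The baseline is the mean pupil size over the pre-cue window
#' (closed-open: the sample at cue onset belongs to the stimulus). The
#' tonic mean is the across-trial average of baselines; the tonic SD is
#' their n-1 sample standard deviation.
#'
#' @param epoch_set An [epoch_series()] result.
#' @param baseline_window Window relative to cue onset, seconds
#'   (default c(-0.5, 0)).
#' @return List of class `baseline_stats`: `per_trial_baseline`,
#'   `tonic_mean`, `tonic_sd`.
#' @export
baseline_stats <- function(epoch_set, baseline_window = c(-0.5, 0)) {
  tt <- epoch_set$epoch_time
  sel <- tt >= baseline_window[1] - 1e-9 & tt < baseline_window[2] - 1e-9
  if (!any(sel)) stop("empty baseline window")
  b <- rowMeans(epoch_set$epochs[, sel, drop = FALSE])
  structure(list(per_trial_baseline = b, tonic_mean = mean(b),
                 tonic_sd = stats::sd(b)),
            class = "baseline_stats")
}

#' Condition-averaged phasic traces
#'
#' Baseline-normalized, condition-averaged pupil time courses for one
#' subject. `zscore` subtracts each trial's baseline, averages within
#' condition, and divides by the subject's tonic SD (the across-trial SD
#' of baselines); `subtract_only` omits the division; `proportional`
#' averages per-trial (epoch - baseline) / baseline.
#'
#' @param epoch_set An [epoch_series()] result.
#' @param baseline A [baseline_stats()] result.
#' @param mode One of `"zscore"`, `"subtract_only"`, `"proportional"`.
#' @param condition A factor/character vector, one entry per trial; traces
#'   are computed per level. Defaults to a single condition `"all"`.
#' @return Named list per condition, each a `phasic_trace`: `trace`,
#'   `mode`, `n_trials_averaged`.
#' @export
phasic <- function(epoch_set, baseline,
                   mode = c("zscore", "subtract_only", "proportional"),
                   condition = NULL) {
  mode <- match.arg(mode)
  n_tr <- nrow(epoch_set$epochs)
  if (is.null(condition)) condition <- rep("all", n_tr)
  if (length(condition) != n_tr)
    stop("condition must have one entry per trial")
  if (mode == "zscore" && baseline$tonic_sd <= 0)
    stop("degenerate baseline distribution: tonic_sd = 0")
  b <- baseline$per_trial_baseline
  corrected <- switch(mode,
    zscore = ,
    subtract_only = epoch_set$epochs - b,
    proportional = (epoch_set$epochs - b) / b)
  lapply(split(seq_len(n_tr), condition), function(idx) {
    avg <- colMeans(corrected[idx, , drop = FALSE])
    if (mode == "zscore") avg <- avg / baseline$tonic_sd
    structure(list(trace = avg, time = epoch_set$epoch_time, mode = mode,
                   n_trials_averaged = length(idx)),
              class = "phasic_trace")
  })
}

#' Write / read a pupil series as CSV
#'
#' Columns `time_s`, `pupil`, `valid` (0/1), with a header row.
#'
#' @param series A [sample_series()].
#' @param path File path.
#' @param sampling_rate Hz (for `read_sample_series`; inferred from the
#'   time column when NULL).
#' @return `write_sample_series()` returns `path` invisibly.
#' @export
write_sample_series <- function(series, path) {
  utils::write.csv(data.frame(time_s = series$time, pupil = series$pupil,
                              valid = as.integer(series$valid)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_series
#' @export
read_sample_series <- function(path, sampling_rate = NULL) {
  df <- utils::read.csv(path)
  if (is.null(sampling_rate))
    sampling_rate <- 1 / stats::median(diff(df$time_s))
  sample_series(df$time_s, df$pupil, df$valid != 0, sampling_rate)
}
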