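#' Impulse response container
#'
#' @param samples Amplitude sequence.
#' @param sampling_rate Hz.
#' @return List of class `impulse_response`.
#' @export
impulse_response <- function(samples, sampling_rate) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate),
            class = "impulse_response")
}

#' Recover an impulse response by sweep deconvolution
#'
#' Divides the spectrum of the recorded sweep response by the spectrum of
#' the reference sweep, with Tikhonov-style regularization
#' H = R conj(S) / (|S|^2 + eps) to keep out-of-band bins bounded, then
#' inverse-transforms.
#'
#' @param recording Recorded response samples.
#' @param sweep Reference sweep samples (same sampling rate).
#' @param sampling_rate Hz.
#' @param regularization eps; defaults to 1e-8 times the sweep's maximum
#'   spectral power.
#' @return An [impulse_response()] of the recording's length (lags 0..).
#' @export
deconvolve_sweep <- function(recording, sweep, sampling_rate,
                             regularization = NULL) {
  if (all(sweep == 0)) stop("zero sweep: cannot deconvolve")
  nfft <- 2^ceiling(log2(length(recording) + length(sweep)))
  R <- stats::fft(c(recording, rep(0, nfft - length(recording))))
  S <- stats::fft(c(sweep, rep(0, nfft - length(sweep))))
  pow <- Mod(S)^2
  if (is.null(regularization)) regularization <- 1e-8 * max(pow)
  H <- R * Conj(S) / (pow + regularization)
  ir <- Re(stats::fft(H, inverse = TRUE)) / nfft
  impulse_response(ir[seq_len(length(recording))], sampling_rate)
}

#' RT60 by Schroeder backward integration
#'
#' The energy decay curve is EDC(t) = 10 log10(int_t^T h^2 / int_0^T h^2);
#' a straight line is fit over `fit_range` (default -5 to -25 dB, the T20
#' range) and extrapolated to -60 dB: RT60 = -60 / slope.
#'
#' @param ir An [impulse_response()].
#' @param fit_range Decay range in dB, default c(-5, -25).
#' @return List of class `acoustic_result`: `rt60` (s),
#'   `decay_fit_range`, `fit_r_squared`, `slope_db_per_s`, `edc_db`.
#' @export
schroeder_rt60 <- function(ir, fit_range = c(-5, -25)) {
  stopifnot(inherits(ir, "impulse_response"))
  h <- ir$samples
  fs <- ir$sampling_rate
  e <- rev(cumsum(rev(h^2)))
  if (e[1] <= 0) stop("insufficient decay: silent response")
  edc <- 10 * log10(pmax(e / e[1], .Machine$double.xmin))
  tt <- (seq_along(h) - 1) / fs
  hi <- max(fit_range); lo <- min(fit_range)
  sel <- which(edc <= hi & edc >= lo)
  if (length(sel) < 10)
    stop("insufficient decay: EDC does not span the fit range")
  fit <- stats::lm(edc[sel] ~ tt[sel])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) stop("insufficient decay: non-decaying EDC")
  structure(list(rt60 = -60 / slope,
                 decay_fit_range = c(hi, lo),
                 fit_r_squared = summary(fit)$r.squared,
                 slope_db_per_s = slope,
                 edc_db = edc),
            class = "acoustic_result")
}

#' Truncate an impulse response to its direct path
#'
#' Detects the direct-path onset as the first sample exceeding 10% of the
#' absolute peak, keeps `window_length` seconds from there, applies an
#' optional raised-cosine taper at the cut, and zeroes the rest
#' (pseudo-anechoic truncation).
#'
#' @param ir An [impulse_response()].
#' @param window_length Seconds kept after the direct-path onset.
#' @param taper `"raised_cosine"` (default) or `"none"`.
#' @param taper_length Taper duration, seconds (default 1 ms).
#' @return The windowed [impulse_response()], same length.
#' @export
window_direct_path <- function(ir, window_length,
                               taper = c("raised_cosine", "none"),
                               taper_length = 0.001) {
  taper <- match.arg(taper)
  stopifnot(inherits(ir, "impulse_response"))
  h <- ir$samples
  fs <- ir$sampling_rate
  onset <- which(abs(h) > 0.1 * max(abs(h)))[1]
  win_n <- as.integer(round(window_length * fs))
  cut <- onset + win_n - 1L
  if (cut >= length(h)) stop("window longer than the response")
  w <- numeric(length(h))
  w[seq_len(cut)] <- 1
  if (taper == "raised_cosine") {
    tn <- min(as.integer(round(taper_length * fs)), cut - 1L)
    if (tn > 0) {
      idx <- (cut - tn + 1L):cut
      w[idx] <- 0.5 * (1 + cos(pi * seq_len(tn) / tn))
    }
  }
  impulse_response(h * w, fs)
}

#' Read / write amplitude sequences as CSV
#'
#' Single column `amplitude` with a header; the sampling rate travels
#' separately (or in the paired JSON result files).
#'
#' @param samples Numeric amplitudes (write) / file path (read).
#' @param path File path.
#' @return `read_amplitude_csv()` returns a numeric vector.
#' @export
write_amplitude_csv <- function(samples, path) {
  utils::write.csv(data.frame(amplitude = samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_amplitude_csv
#' @export
read_amplitude_csv <- function(path) {
  utils::read.csv(path)$amplitude
}
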