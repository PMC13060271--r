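# IIR filter design and zero-phase application in base R.
# No signal-processing package is assumed; the Butterworth lowpass is
# designed by bilinear transform of the analog prototype and applied with
# stats::filter (convolution pass for the numerator, recursive pass for
# the denominator), which keeps everything vectorized.

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - ri * c(0, coef)
  coef
}

#' Digital Butterworth lowpass coefficients
#'
#' Designs an order-`order` lowpass Butterworth filter at `cutoff` Hz for a
#' sampling rate `fs` Hz via the bilinear transform with frequency
#' pre-warping (matching the conventional digital design).
#'
#' @param order Filter order (default 4).
#' @param cutoff -3 dB cutoff frequency, Hz.
#' @param fs Sampling rate, Hz; `cutoff` must be below `fs / 2`.
#' @return List with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @export
butter_lowpass <- function(order = 4, cutoff, fs) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0 || order < 1) stop("invalid filter parameters")
  wn <- cutoff / (fs / 2)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # analog prototype
  fs2 <- 2
  warped <- 2 * fs2 * tan(pi * wn / 2)
  p <- p * warped
  gain <- warped^order
  # bilinear transform: s -> 2*fs2*(z-1)/(z+1)
  pz <- (2 * fs2 + p) / (2 * fs2 - p)
  gain <- gain * Re(1 / prod(2 * fs2 - p))
  a <- Re(poly_from_roots(pz))
  b <- gain * Re(poly_from_roots(rep(-1 + 0i, order)))
  list(b = b / a[1], a = a / a[1])
}

#' Direct-form IIR filtering (zero initial state)
#'
#' @param b,a Filter coefficients.
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# samples needed for the slowest pole transient to decay below 1e-8
settle_length <- function(a) {
  if (length(a) <= 1) return(1L)
  r <- max(Mod(polyroot(rev(a))))
  if (r >= 1) return(NA_integer_)
  as.integer(ceiling(log(1e-8) / log(r)))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward so the net response is the
#' squared magnitude with zero phase. Edge transients are controlled by
#' odd-symmetric signal extension sized from the slowest pole's decay.
#'
#' @param b,a Filter coefficients.
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, settle_length(a))
  if (is.na(pad)) stop("unstable filter")
  ext <- c(2 * x[1] - x[seq(pad + 1, 2)],
           x,
           2 * x[n] - x[seq(n - 1, n - pad)])
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Analytic Butterworth magnitude response
#'
#' |H(f)| = 1 / sqrt(1 + (f / cutoff)^(2 * order)) for the analog
#' prototype; the zero-phase (two-pass) gain is its square.
#'
#' @param f Frequency, Hz.
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order.
#' @return Single-pass magnitude gain at `f`.
#' @export
butterworth_gain <- function(f, cutoff, order = 4) {
  1 / sqrt(1 + (f / cutoff)^(2 * order))
}
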