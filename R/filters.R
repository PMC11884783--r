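#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) FIR bandpass applied forward and backward
#' (zero net phase). The default order follows the rule of three cycles
#' of the low-frequency cut-off: `order = round(3 * fs / band[1])`.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param band length-2 numeric, passband edges in Hz; must lie inside
#'   `(0, fs/2)`.
#' @param order filter order (number of taps - 1); default from the
#'   3-cycle rule.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_fir <- function(x, fs, band, order = NULL) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (band[2] >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency")
  if (is.null(order)) order <- round(3 * fs / band[1])
  order <- max(6L, as.integer(order))
  if (order %% 2 == 1) order <- order + 1L
  if (length(x) < 3 * (order + 1))
    stop("signal shorter than 3 times the filter length (",
         3 * (order + 1), " samples needed)")
  b <- signal::fir1(order, band / (fs / 2), type = "pass")
  filtfilt_fft(b, x)
}

# forward-backward FIR filtering via FFT convolution with reflection
# padding; exact zero phase for any FIR.
filtfilt_fft <- function(b, x) {
  nb <- length(b)
  n <- length(x)
  npad <- min(n - 1, 3 * nb)
  xp <- c(rev(x[2:(npad + 1)]), x, rev(x[(n - npad):(n - 1)]))
  y <- fft_conv_same(xp, b)
  y <- rev(fft_conv_same(rev(y), b))
  y[(npad + 1):(npad + n)]
}

# linear convolution, centered ("same") output, via FFT
fft_conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  L <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, numeric(L - n)))
  K <- stats::fft(c(k, numeric(L - m)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / L
  lag <- floor((m - 1) / 2)
  y[(lag + 1):(lag + n)]
}

#' Analytic signal via the Hilbert transform
#'
#' @param x numeric signal (will have its mean removed).
#' @return complex analytic signal; `Mod()` is the instantaneous
#'   amplitude, `Arg()` the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited component
#'
#' Bandpasses the signal ([bandpass_fir()]) and returns the phase of its
#' analytic signal. Cosine convention: phase 0 at waveform peaks,
#' +/- pi at troughs.
#'
#' @inheritParams bandpass_fir
#' @return phase series in radians, in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(x, fs, band, order = NULL) {
  Arg(analytic_signal(bandpass_fir(x, fs, band, order)))
}

#' Gaussian smoothing
#'
#' Convolves with a Gaussian kernel of total width `window_s` seconds
#' (kernel SD = window / 6), edge-corrected by normalizing with the
#' convolved window.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param window_s window length in seconds.
#' @return smoothed signal, same length.
#' @export
gaussian_smooth <- function(x, fs, window_s) {
  len <- max(3L, round(window_s * fs))
  if (len %% 2 == 0) len <- len + 1L
  s <- len / 6
  k <- stats::dnorm(seq(-(len - 1) / 2, (len - 1) / 2), sd = s)
  k <- k / sum(k)
  num <- fft_conv_same(x, k)
  den <- fft_conv_same(rep(1, length(x)), k)
  num / den
}

#' Root-mean-square envelope
#'
#' Instantaneous squared signal, Gaussian-smoothed over `window_s`,
#' then square-rooted.
#'
#' @inheritParams gaussian_smooth
#' @export
rms_envelope <- function(x, fs, window_s) {
  sqrt(pmax(gaussian_smooth(x^2, fs, window_s), 0))
}
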