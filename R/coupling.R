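# Event-locked time-frequency analysis, the synchronization-index (SI)
# statistic for slow-wave/spindle phase-amplitude coupling, circular
# statistics, nearest-event pairing, spectra/coherence/cross-correlation
# and event-locked wavelet averages.

#' Synchronization index of two phase series
#'
#' `SI = (1/m) * sum_j exp(i * (theta_ref(j) - theta_amp(j)))` over the
#' `m` aligned time points. `|SI|` in `[0, 1]` is the coupling strength;
#' `Arg(SI)` the preferred phase shift.
#'
#' @param ref_phase,amp_phase phase series in radians, aligned on the
#'   same time grid.
#' @return list with `si` (complex), `strength`, `angle` (radians),
#'   `angle_deg`, `m`.
#' @export
synchronization_index <- function(ref_phase, amp_phase) {
  stopifnot(length(ref_phase) == length(amp_phase))
  ok <- is.finite(ref_phase) & is.finite(amp_phase)
  m <- sum(ok)
  if (m == 0) stop("no aligned time points (m = 0)")
  si <- mean(exp(1i * (ref_phase[ok] - amp_phase[ok])))
  list(si = si, strength = Mod(si), angle = Arg(si),
       angle_deg = Arg(si) * 180 / pi, m = m)
}

#' Slow-wave/spindle coupling via the synchronization index
#'
#' Computes, per detected slow wave, the SI between the slow-wave phase
#' of `x_sw` and the phase of spindle-band amplitude fluctuations of
#' `x_amp`, in a window around the slow-wave reference point. The
#' amplitude phase is obtained by bandpassing `x_amp` in `amp_band`,
#' taking the Hilbert amplitude envelope, filtering the envelope in the
#' slow-wave band and taking its Hilbert phase.
#'
#' @param x_sw signal supplying the slow-wave phase (e.g. cortical
#'   trace).
#' @param x_amp signal supplying the fast-band amplitude (same length
#'   and rate; may equal `x_sw`).
#' @param fs sampling rate, Hz.
#' @param events slow-wave event table (from [detect_slow_waves()]).
#' @param ref reference time column: `"peak_s"` (experimental
#'   convention) or `"trough_s"` (model down-state convention).
#' @param window half-window around the reference, s (default 0.25).
#' @param sw_band slow-wave band, Hz.
#' @param amp_band fast band whose envelope is analyzed, Hz.
#' @param t0 time of the first sample, s.
#' @return data.frame with one row per usable event: `strength`,
#'   `angle_deg`, `m`.
#' @export
sw_spindle_coupling <- function(x_sw, x_amp, fs, events, ref = "peak_s",
                                window = 0.25, sw_band = c(0.5, 2),
                                amp_band = c(7, 15), t0 = 0) {
  stopifnot(length(x_sw) == length(x_amp), ref %in% names(events))
  ph_sw <- instantaneous_phase(x_sw, fs, sw_band)
  env <- Mod(analytic_signal(bandpass_fir(x_amp, fs, amp_band)))
  ph_amp <- Arg(analytic_signal(bandpass_fir(env, fs, sw_band)))
  n <- length(x_sw)
  w <- round(window * fs)
  out <- lapply(events[[ref]], function(tt) {
    i <- round((tt - t0) * fs) + 1L
    if (i - w < 1 || i + w > n) return(NULL)
    idx <- (i - w):(i + w)
    si <- synchronization_index(ph_sw[idx], ph_amp[idx])
    data.frame(ref_s = tt, strength = si$strength,
               angle_deg = si$angle_deg, m = si$m)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(ref_s = numeric(),
                                      strength = numeric(),
                                      angle_deg = numeric(), m = integer())
  out
}

#' Circular summary statistics
#'
#' Mean direction, resultant length, circular SD and the Rayleigh test
#' of uniformity (large-sample approximation
#' `p = exp(-Z) * (1 + (2Z - Z^2) / (4n))` with `Z = n R^2`).
#'
#' @param phases phases in radians.
#' @return list with `n`, `mean_deg`, `mean_rad`, `R` (resultant
#'   length), `circ_sd_deg`, `rayleigh_z`, `p`.
#' @export
circular_summary <- function(phases) {
  phases <- phases[is.finite(phases)]
  n <- length(phases)
  if (n < 2) stop("need at least 2 phases")
  z <- mean(exp(1i * phases))
  R <- Mod(z)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n))
  p <- min(max(p, 0), 1)
  list(n = n, mean_rad = Arg(z), mean_deg = Arg(z) * 180 / pi, R = R,
       circ_sd_deg = sqrt(-2 * log(max(R, 1e-12))) * 180 / pi,
       rayleigh_z = Z, p = p)
}

#' Watson-Williams test for equality of two mean directions
#'
#' Classical one-way test with the `1 + 3/(8*kappa)` correction factor.
#'
#' @param a,b phase samples in radians.
#' @return list with `F`, `df1`, `df2`, `p`, and the two mean
#'   directions in degrees.
#' @export
watson_williams <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n1 < 5 || n2 < 5) stop("need at least 5 phases per sample")
  R1 <- Mod(sum(exp(1i * a))); R2 <- Mod(sum(exp(1i * b)))
  R <- Mod(sum(exp(1i * c(a, b))))
  rbar <- (R1 + R2) / n
  # ML estimate of the concentration parameter (standard approximation)
  kappa <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
  else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * (n - 2) * (R1 + R2 - R) / (n - R1 - R2)
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(F = Fstat, df1 = 1, df2 = n - 2, p = p,
       mean_deg = c(Arg(sum(exp(1i * a))), Arg(sum(exp(1i * b)))) * 180 / pi)
}

#' Pair each event with the nearest event of another set
#'
#' For each event in `a`, the nearest event in `b` (by onset) within
#' `max_gap` seconds. Delay is `b$onset_s - a$onset_s`; a negative
#' median delay means `b` tends to precede `a`. A Wilcoxon signed-rank
#' test of zero median delay is included.
#'
#' @param a,b event tables (sorted by onset).
#' @param max_gap maximum |delay| allowed, s.
#' @param by time column used for pairing (default `"onset_s"`).
#' @return list with `pairs` (data.frame: a_time, b_time, delay_s,
#'   a_amplitude, b_amplitude), `median_delay_s`, `p_wilcoxon`,
#'   `amplitude_cor` (Pearson, NA if < 3 pairs).
#' @export
pair_nearest_events <- function(a, b, max_gap = Inf, by = "onset_s") {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(list(pairs = data.frame(), median_delay_s = NA_real_,
                p_wilcoxon = NA_real_, amplitude_cor = NA_real_))
  ta <- a[[by]]; tb <- b[[by]]
  j <- findInterval(ta, tb)
  lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(tb))
  pick <- ifelse(abs(tb[lo] - ta) <= abs(tb[hi] - ta), lo, hi)
  delay <- tb[pick] - ta
  keep <- abs(delay) <= max_gap
  pairs <- data.frame(a_time = ta[keep], b_time = tb[pick][keep],
                      delay_s = delay[keep],
                      a_amplitude = a$amplitude[keep],
                      b_amplitude = b$amplitude[pick][keep])
  med <- if (nrow(pairs)) stats::median(pairs$delay_s) else NA_real_
  pw <- if (nrow(pairs) >= 5 && stats::sd(pairs$delay_s) > 0)
    stats::wilcox.test(pairs$delay_s, exact = FALSE)$p.value else NA_real_
  ac <- if (nrow(pairs) >= 3 && stats::sd(pairs$a_amplitude) > 0 &&
            stats::sd(pairs$b_amplitude) > 0)
    stats::cor(pairs$a_amplitude, pairs$b_amplitude) else NA_real_
  list(pairs = pairs, median_delay_s = med, p_wilcoxon = pw,
       amplitude_cor = ac)
}

#' Rate histogram of point events around reference events
#'
#' Counts point events (e.g. SWRs) in bins relative to reference onsets
#' (e.g. spindle onsets), expressed as a rate (events/s per reference).
#' Significance band from surrogates in which each point event is
#' independently jittered uniformly within +/- `shuffle_window_s`
#' (seeded).
#'
#' @param point_events,reference_events event tables.
#' @param window half-window, s.
#' @param bin bin width, s.
#' @param n_shuffles number of surrogate shuffles.
#' @param shuffle_window_s half-width of the event-time jitter, s.
#' @param point_time,ref_time time columns used.
#' @param seed RNG seed for the shuffles.
#' @return list with `mids` (bin centers, s), `rate`, `shuffle_mean`,
#'   `shuffle_lo`, `shuffle_hi` (2.5/97.5 percentiles), `n_ref`,
#'   `peak_time_s` (bin center of the maximal rate).
#' @export
event_rate_histogram <- function(point_events, reference_events,
                                 window = 1, bin = 0.1, n_shuffles = 100,
                                 shuffle_window_s = 0.5,
                                 point_time = "peak_s",
                                 ref_time = "onset_s", seed = 1) {
  stopifnot(nrow(point_events) > 0, nrow(reference_events) > 0)
  tp <- point_events[[point_time]]
  tref <- reference_events[[ref_time]]
  breaks <- seq(-window, window, by = bin)
  mids <- breaks[-1] - bin / 2
  count_rel <- function(tp) {
    rel <- unlist(lapply(tref, function(r) {
      d <- tp - r
      d[d >= -window & d < window]
    }))
    if (!length(rel)) return(numeric(length(mids)))
    graphics::hist(rel, breaks = breaks, plot = FALSE)$counts
  }
  obs <- count_rel(tp) / (length(tref) * bin)
  if (!is.null(seed)) set.seed(seed)
  sur <- replicate(n_shuffles, {
    count_rel(tp + stats::runif(length(tp), -shuffle_window_s,
                                shuffle_window_s)) /
      (length(tref) * bin)
  })
  list(mids = mids, rate = obs,
       shuffle_mean = rowMeans(sur),
       shuffle_lo = apply(sur, 1, stats::quantile, 0.025),
       shuffle_hi = apply(sur, 1, stats::quantile, 0.975),
       n_ref = length(tref),
       peak_time_s = mids[which.max(obs)])
}

#' Event-locked time-frequency representation
#'
#' Short-time Fourier amplitude with a Hanning taper whose length is
#' `n_cycles` cycles of each frequency, evaluated on a `step_s` grid,
#' averaged across events and normalized as percent change from the
#' per-frequency mean over a pre-event baseline window.
#'
#' @param x signal.
#' @param fs sampling rate, Hz.
#' @param event_times event reference times, s.
#' @param freqs frequencies of interest, Hz.
#' @param window time window around each event, s (length 2).
#' @param baseline baseline window for percent change, s relative to the
#'   event (default `c(-3.5, -2.5)`); `NULL` for raw amplitude.
#' @param step_s time step of the TFR grid (default 0.01).
#' @param n_cycles taper length in cycles per frequency (default 5).
#' @param t0 time of the first sample, s.
#' @return list with `times` (s, relative), `freqs`, `tfr` (freq x time
#'   matrix, percent change or raw amplitude), `n_events`, `n_dropped`.
#' @export
event_locked_tfr <- function(x, fs, event_times, freqs,
                             window = c(-1, 1), baseline = c(-3.5, -2.5),
                             step_s = 0.01, n_cycles = 5, t0 = 0) {
  lo <- min(window[1], if (is.null(baseline)) window[1] else baseline[1])
  hi <- max(window[2], if (is.null(baseline)) window[2] else baseline[2])
  max_half <- max(round(n_cycles * fs / freqs) %/% 2)
  n <- length(x)
  grid <- seq(lo, hi, by = step_s)
  keep <- vapply(event_times, function(tt) {
    i <- round((tt - t0) * fs) + 1L
    i + round(lo * fs) - max_half >= 1 && i + round(hi * fs) + max_half <= n
  }, logical(1))
  dropped <- sum(!keep)
  ev <- event_times[keep]
  if (!length(ev)) stop("no events with sufficient margin")
  amp <- array(0, c(length(freqs), length(grid)))
  for (fi in seq_along(freqs)) {
    half <- round(n_cycles * fs / freqs[fi]) %/% 2
    taper <- signal::hanning(2 * half + 1)
    taper <- taper / sum(taper)
    carr <- exp(-2i * pi * freqs[fi] * (seq(-half, half) / fs)) * taper
    for (tt in ev) {
      i0 <- round((tt - t0) * fs) + 1L
      centers <- i0 + round(grid * fs)
      vals <- vapply(centers, function(cc)
        Mod(sum(x[(cc - half):(cc + half)] * carr)), numeric(1))
      amp[fi, ] <- amp[fi, ] + vals
    }
  }
  amp <- amp / length(ev)
  times <- grid
  if (!is.null(baseline)) {
    bsel <- times >= baseline[1] & times <= baseline[2]
    base <- rowMeans(amp[, bsel, drop = FALSE])
    amp <- 100 * (amp - base) / base
  }
  wsel <- times >= window[1] & times <= window[2]
  list(times = times[wsel], freqs = freqs,
       tfr = amp[, wsel, drop = FALSE],
       n_events = length(ev), n_dropped = dropped)
}

#' Welch spectra, coherence and band-limited cross-correlation
#'
#' Hann-tapered Welch averages with 50 percent overlap; magnitude-squared
#' coherence; cross-correlation (optionally after bandpassing) with the
#' lag of its absolute peak (positive lag means `y` lags `x`).
#'
#' @param x,y signals of equal length.
#' @param fs sampling rate, Hz.
#' @param seg_s Welch segment length, s.
#' @param max_lag_s maximum cross-correlation lag, s.
#' @param xcorr_band optional band (Hz) applied before cross-correlation.
#' @return list with `freq`, `pxx`, `pyy`, `coherence`, `xcorr`
#'   (data.frame lag_s, r), `peak_lag_s`, `peak_r`.
#' @export
spectral_summary <- function(x, y, fs, seg_s = 4, max_lag_s = 0.5,
                             xcorr_band = NULL) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (length(x) < 10 * fs) stop("need at least 10 s of signal")
  nseg <- round(seg_s * fs)
  step <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- signal::hanning(nseg)
  U <- sum(w^2)
  nf <- nseg %/% 2
  Pxx <- Pyy <- numeric(nf); Pxy <- complex(nf)
  for (s0 in starts) {
    xs <- (x[s0:(s0 + nseg - 1)] - mean(x[s0:(s0 + nseg - 1)])) * w
    ys <- (y[s0:(s0 + nseg - 1)] - mean(y[s0:(s0 + nseg - 1)])) * w
    X <- stats::fft(xs)[1:nf]; Y <- stats::fft(ys)[1:nf]
    Pxx <- Pxx + Mod(X)^2 / U; Pyy <- Pyy + Mod(Y)^2 / U
    Pxy <- Pxy + X * Conj(Y) / U
  }
  k <- length(starts)
  Pxx <- Pxx / k; Pyy <- Pyy / k; Pxy <- Pxy / k
  coh <- Mod(Pxy)^2 / (Pxx * Pyy)
  freq <- (seq_len(nf) - 1) * fs / nseg
  xb <- x; yb <- y
  if (!is.null(xcorr_band)) {
    xb <- bandpass_fir(x, fs, xcorr_band)
    yb <- bandpass_fir(y, fs, xcorr_band)
  }
  ml <- round(max_lag_s * fs)
  cc <- stats::ccf(yb, xb, lag.max = ml, plot = FALSE)
  lag_s <- as.numeric(cc$lag) / fs
  r <- as.numeric(cc$acf)
  ipk <- which.max(abs(r))
  list(freq = freq, pxx = Pxx, pyy = Pyy, coherence = coh,
       xcorr = data.frame(lag_s = lag_s, r = r),
       peak_lag_s = lag_s[ipk], peak_r = r[ipk])
}

#' Event-locked average wavelet scalogram
#'
#' Morlet continuous wavelet transform magnitude of epochs around event
#' times, averaged over events. Epochs are extracted at the given epoch
#' length, downsampled to `target_fs`, and analyzed on a logarithmic
#' frequency grid (`voices` per octave between `flim`).
#'
#' @param x signal.
#' @param fs sampling rate, Hz.
#' @param event_times event reference times, s.
#' @param epoch_s epoch length centered on each event, s (default 5).
#' @param target_fs analysis rate after downsampling (default 250).
#' @param flim frequency limits, Hz (default `c(0.1, 50)`).
#' @param voices voices per octave (default 20).
#' @param omega0 Morlet carrier parameter (default 6).
#' @param t0 time of the first sample, s.
#' @return list with `times` (s, relative), `freqs`, `mag` (freq x time
#'   average magnitude), `n_events`.
#' @export
event_locked_wavelet_average <- function(x, fs, event_times, epoch_s = 5,
                                         target_fs = 250,
                                         flim = c(0.1, 50), voices = 20,
                                         omega0 = 6, t0 = 0) {
  dec <- max(1L, round(fs / target_fs))
  fs2 <- fs / dec
  if (flim[2] >= fs2 / 2) stop("upper frequency limit above Nyquist")
  half <- round(epoch_s / 2 * fs)
  n <- length(x)
  keep <- vapply(event_times, function(tt) {
    i <- round((tt - t0) * fs) + 1L
    i - half >= 1 && i + half <= n
  }, logical(1))
  ev <- event_times[keep]
  if (!length(ev)) stop("no events with sufficient margin")
  noct <- log2(flim[2] / flim[1])
  freqs <- flim[1] * 2^(seq(0, noct, by = 1 / voices))
  i0 <- round((ev[1] - t0) * fs) + 1L
  idx <- seq(i0 - half, i0 + half, by = dec)
  nt <- length(idx)
  omega <- 2 * pi * c(seq(0, floor(nt / 2)),
                      seq(-(ceiling(nt / 2) - 1), -1)) * fs2 / nt
  acc <- array(0, c(length(freqs), nt))
  for (tt in ev) {
    i0 <- round((tt - t0) * fs) + 1L
    seg <- x[seq(i0 - half, i0 + half, by = dec)]
    S <- stats::fft(seg - mean(seg))
    for (fi in seq_along(freqs)) {
      scale <- omega0 / (2 * pi * freqs[fi])
      psi <- sqrt(2 * pi * scale * fs2) * pi^(-0.25) *
        exp(-(scale * omega - omega0)^2 / 2) * (omega > 0)
      wt <- stats::fft(S * psi, inverse = TRUE) / nt
      acc[fi, ] <- acc[fi, ] + Mod(wt)
    }
  }
  list(times = (seq_len(nt) - 1 - (nt - 1) / 2) / fs2, freqs = freqs,
       mag = acc / length(ev), n_events = length(ev))
}
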