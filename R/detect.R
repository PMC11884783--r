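# Detection of NREM sleep events (slow waves, spindles, sharp-wave
# ripples) from continuous signals, restricted to NREM epochs of a
# hypnogram. Thresholds are in SD (or median + SD for SWRs) of the
# relevant detection signal computed over NREM samples only.

#' Construct an event table
#'
#' @param kind event kind (`"slow_wave"`, `"spindle"`, `"swr"`, ...).
#' @param onset,peak,offset event times in seconds from recording start;
#'   intervals are half-open `[onset, offset)`.
#' @param amplitude event amplitude in signal units.
#' @param channel channel identifier.
#' @param ... further per-event columns (e.g. `trough_s` for slow waves).
#' @return a `data.frame` with columns kind, channel, onset_s, peak_s,
#'   offset_s, amplitude (plus extras), sorted by onset.
#' @export
events_table <- function(kind = character(), onset = numeric(),
                         peak = numeric(), offset = numeric(),
                         amplitude = numeric(), channel = NA_character_,
                         ...) {
  if (length(kind) == 0) channel <- character()
  df <- data.frame(kind = as.character(kind),
                   channel = as.character(channel),
                   onset_s = as.numeric(onset), peak_s = as.numeric(peak),
                   offset_s = as.numeric(offset),
                   amplitude = as.numeric(amplitude),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df[order(df$onset_s), , drop = FALSE]
}

#' All-NREM hypnogram
#'
#' Convenience constructor labelling an entire recording as NREM (used
#' for model output, where the simulated regime is NREM throughout).
#'
#' @param duration_s recording duration in seconds.
#' @param epoch_s epoch length (default 20 s).
#' @return a hypnogram `data.frame` (epoch_start_s, epoch_end_s, label).
#' @export
hypnogram_all_nrem <- function(duration_s, epoch_s = 20) {
  starts <- seq(0, duration_s - 1e-9, by = epoch_s)
  data.frame(epoch_start_s = starts,
             epoch_end_s = pmin(starts + epoch_s, duration_s),
             label = "NREM", stringsAsFactors = FALSE)
}

# logical mask of samples inside NREM epochs
nrem_mask <- function(hypnogram, n, fs, t0 = 0) {
  m <- logical(n)
  hp <- hypnogram[hypnogram$label == "NREM", , drop = FALSE]
  for (i in seq_len(nrow(hp))) {
    a <- max(1L, floor((hp$epoch_start_s[i] - t0) * fs) + 1L)
    b <- min(n, ceiling((hp$epoch_end_s[i] - t0) * fs))
    if (b >= a) m[a:b] <- TRUE
  }
  m
}

# index runs where `ok` is TRUE; returns two-column matrix (start, end)
runs_true <- function(ok) {
  r <- rle(as.vector(ok))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# drop events that touch a non-NREM sample (epoch-boundary truncation)
inside_mask <- function(ev, mask, fs, t0 = 0) {
  if (nrow(ev) == 0) return(ev)
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    a <- max(1L, floor((ev$onset_s[i] - t0) * fs) + 1L)
    b <- min(length(mask), ceiling((ev$offset_s[i] - t0) * fs))
    b >= a && all(mask[a:b])
  }, logical(1))
  ev[keep, , drop = FALSE]
}

local_maxima <- function(x) which(diff(sign(diff(x))) == -2) + 1L
local_minima <- function(x) which(diff(sign(diff(x))) == 2) + 1L

#' Detect slow waves
#'
#' The 0.5-4 Hz bandpassed signal yields tentative events whose positive
#' peak exceeds `peak_sd` SDs and whose positive-to-negative
#' peak-to-peak difference exceeds `p2p_sd` SDs (SDs over NREM samples).
#' A tentative event is kept only when its positive peak falls between
#' two consecutive positive-to-negative zero crossings of the 0.5-2 Hz
#' signal that are 0.5-2 s apart. Event peak time is the positive peak;
#' the trough time (negative peak, the down state) is also reported,
#' supporting both the experimental (peak) and model (trough) reference
#' conventions.
#'
#' @param x signal (LFP or model membrane potential).
#' @param fs sampling rate, Hz.
#' @param hypnogram hypnogram `data.frame`; only NREM epochs are used.
#' @param peak_sd,p2p_sd threshold multipliers (defaults 2.5 and 4).
#' @param cycle_range allowed zero-crossing spacing, s (default
#'   `c(0.5, 2)`).
#' @param channel channel label for the event table.
#' @param t0 time of the first sample, s.
#' @return event table with extra column `trough_s`.
#' @export
detect_slow_waves <- function(x, fs, hypnogram, peak_sd = 2.5, p2p_sd = 4,
                              cycle_range = c(0.5, 2), channel = "lfp",
                              t0 = 0) {
  mask <- nrem_mask(hypnogram, length(x), fs, t0)
  empty <- events_table(trough_s = numeric())
  if (!any(mask)) {
    warning("no NREM epochs; returning empty event set")
    return(empty)
  }
  x4 <- bandpass_fir(x, fs, c(0.5, 4))
  x2 <- bandpass_fir(x, fs, c(0.5, 2))
  s4 <- stats::sd(x4[mask])
  if (s4 == 0) stop("zero-variance signal")
  # consecutive positive-to-negative zero crossings of the 0.5-2 Hz signal
  dn <- which(x2[-length(x2)] > 0 & x2[-1] <= 0)
  if (length(dn) < 2) return(empty)
  span_ok <- diff(dn) / fs >= cycle_range[1] & diff(dn) / fs <= cycle_range[2]
  pk <- local_maxima(x4)
  pk <- pk[x4[pk] > peak_sd * s4 & mask[pk]]
  res <- lapply(pk, function(i) {
    # enclosing down-crossing pair in the 0.5-2 Hz signal
    j <- findInterval(i, dn)
    if (j < 1 || j >= length(dn) || !span_ok[j]) return(NULL)
    a <- dn[j]; b <- dn[j + 1]
    seg <- x4[a:b]
    tr4 <- which.min(seg) + a - 1L
    if (x4[i] - x4[tr4] <= p2p_sd * s4) return(NULL)
    # down-state (trough) time from the 0.5-2 Hz signal that defines
    # the slow-wave cycle
    tr2 <- which.min(x2[a:b]) + a - 1L
    c(onset = a, peak = i, offset = b, trough = tr2,
      amp = x4[i] - x4[tr4])
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0) return(empty)
  res <- res[!duplicated(res[, "onset"]), , drop = FALSE]
  ev <- events_table(kind = "slow_wave", channel = channel,
                     onset = t0 + (res[, "onset"] - 1) / fs,
                     peak = t0 + (res[, "peak"] - 1) / fs,
                     offset = t0 + (res[, "offset"] - 1) / fs,
                     amplitude = res[, "amp"],
                     trough_s = t0 + (res[, "trough"] - 1) / fs)
  inside_mask(ev, mask, fs, t0)
}

#' Detect sleep spindles
#'
#' 7-15 Hz bandpass, Hilbert amplitude, 300 ms Gaussian smoothing.
#' Candidates are runs where the smoothed amplitude exceeds
#' `mean + thr_sd * SD` (NREM statistics); onset/offset extend to the
#' `edge_sd` crossings; events closer than `merge_gap_s` are merged;
#' final events must last between `min_dur_s` and `max_dur_s`. Event
#' time is the largest amplitude peak.
#'
#' @inheritParams detect_slow_waves
#' @param band spindle band, Hz.
#' @param smooth_s Gaussian smoothing window, s.
#' @param thr_sd,edge_sd detection and onset/offset thresholds (SD units).
#' @param merge_gap_s merge events closer than this, s.
#' @param min_dur_s,max_dur_s duration gate, s.
#' @export
detect_spindles <- function(x, fs, hypnogram, band = c(7, 15),
                            smooth_s = 0.3, thr_sd = 3, edge_sd = 2.5,
                            merge_gap_s = 0.5, min_dur_s = 0.5,
                            max_dur_s = 3, channel = "lfp", t0 = 0) {
  mask <- nrem_mask(hypnogram, length(x), fs, t0)
  if (!any(mask)) {
    warning("no NREM epochs; returning empty event set")
    return(events_table())
  }
  env <- gaussian_smooth(Mod(analytic_signal(bandpass_fir(x, fs, band))),
                         fs, smooth_s)
  mu <- mean(env[mask]); s <- stats::sd(env[mask])
  if (s == 0) stop("zero-variance envelope")
  hi <- env > mu + thr_sd * s
  lo <- env > mu + edge_sd * s
  if (!any(hi)) return(events_table())
  lo_runs <- runs_true(lo)
  # candidate = lo-run containing at least one hi sample
  hi_any <- cumsum(hi)
  keep <- hi_any[lo_runs[, "end"]] -
    hi_any[pmax(lo_runs[, "start"] - 1L, 1L)] > 0
  cand <- lo_runs[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(events_table())
  # merge candidates separated by < merge_gap_s
  merged <- list(); cur <- cand[1, ]
  for (i in seq_len(nrow(cand))[-1]) {
    if ((cand[i, "start"] - cur["end"]) / fs < merge_gap_s)
      cur["end"] <- cand[i, "end"]
    else { merged[[length(merged) + 1]] <- cur; cur <- cand[i, ] }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)
  dur <- (m[, "end"] - m[, "start"] + 1) / fs
  m <- m[dur >= min_dur_s & dur <= max_dur_s, , drop = FALSE]
  if (nrow(m) == 0) return(events_table())
  pk <- vapply(seq_len(nrow(m)), function(i)
    which.max(env[m[i, "start"]:m[i, "end"]]) + m[i, "start"] - 1L,
    numeric(1))
  ev <- events_table(kind = "spindle", channel = channel,
                     onset = t0 + (m[, "start"] - 1) / fs,
                     peak = t0 + (pk - 1) / fs,
                     offset = t0 + (m[, "end"] - 1) / fs,
                     amplitude = env[pk])
  inside_mask(ev, mask, fs, t0)
}

#' Detect sharp-wave ripples
#'
#' 150-200 Hz bandpass, RMS envelope (squared signal, 50 ms Gaussian
#' smoothing, square root). Events are runs where the envelope exceeds
#' `median + thr_sd * SD` (NREM statistics) for at least `min_dur_s`.
#' Event time is the largest envelope peak.
#'
#' @inheritParams detect_spindles
#' @param band ripple band, Hz.
#' @param min_dur_s minimum supra-threshold duration, s (default 0.03).
#' @export
detect_swrs <- function(x, fs, hypnogram, band = c(150, 200),
                        smooth_s = 0.05, thr_sd = 4, min_dur_s = 0.03,
                        channel = "lfp", t0 = 0) {
  if (fs < 500) stop("sampling rate too low to resolve the ripple band")
  if (band[2] >= fs / 2) stop("ripple band exceeds Nyquist frequency")
  mask <- nrem_mask(hypnogram, length(x), fs, t0)
  if (!any(mask)) {
    warning("no NREM epochs; returning empty event set")
    return(events_table())
  }
  env <- rms_envelope(bandpass_fir(x, fs, band), fs, smooth_s)
  thr <- stats::median(env[mask]) + thr_sd * stats::sd(env[mask])
  if (stats::sd(env[mask]) == 0) stop("zero-variance envelope")
  ok <- env > thr
  if (!any(ok)) return(events_table())
  r <- runs_true(ok)
  r <- r[(r[, "end"] - r[, "start"] + 1) / fs >= min_dur_s, , drop = FALSE]
  if (nrow(r) == 0) return(events_table())
  pk <- vapply(seq_len(nrow(r)), function(i)
    which.max(env[r[i, "start"]:r[i, "end"]]) + r[i, "start"] - 1L,
    numeric(1))
  ev <- events_table(kind = "swr", channel = channel,
                     onset = t0 + (r[, "start"] - 1) / fs,
                     peak = t0 + (pk - 1) / fs,
                     offset = t0 + (r[, "end"] - 1) / fs,
                     amplitude = env[pk])
  inside_mask(ev, mask, fs, t0)
}
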