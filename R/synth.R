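# Seeded synthetic-data generators with exact ground truth for every
# pipeline stage: NREM-like LFP with slow waves, phase-coupled spindles
# and ripple bursts; staged sessions with EMG/EOG; von-Mises
# phase-locked spike trains; evoked intracellular sweeps.

#' 1/f^alpha background noise
#'
#' Gaussian noise spectrally shaped to `1/f^alpha`, scaled to unit SD
#' times `sd`.
#'
#' @param n samples.
#' @param fs sampling rate, Hz.
#' @param alpha spectral exponent (default 1).
#' @param sd target standard deviation.
#' @return numeric vector.
#' @export
pink_noise <- function(n, fs, alpha = 1, sd = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f[1] <- f[2]
  f <- pmin(f, fs - f + f[2])
  W <- W * f^(-alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x) * sd
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection algorithm.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (0 = uniform).
#' @return phases in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
    return(th)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (u[2] < cc * (2 - cc) || u[2] <= cc * exp(1 - cc)) {
      i <- i + 1
      out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  th <- out + mu
  ((th + pi) %% (2 * pi)) - pi
}

# place event times with a minimum spacing by rejection
place_events <- function(duration, rate, min_gap, margin = 2) {
  n_target <- stats::rpois(1, rate * (duration - 2 * margin))
  times <- numeric(0); tries <- 0
  while (length(times) < n_target && tries < 50 * max(n_target, 1)) {
    cand <- stats::runif(1, margin, duration - margin)
    if (!length(times) || all(abs(times - cand) >= min_gap))
      times <- c(times, cand)
    tries <- tries + 1
  }
  sort(times)
}

#' Generate an NREM-like LFP with known slow waves, spindles and SWRs
#'
#' Background `1/f^alpha` noise plus: one-cycle biphasic slow waves
#' (positive then negative half-cycle); Hann-windowed spindle bursts
#' whose envelope peak sits at slow-wave phase `phi0` (von Mises jitter
#' with concentration `kappa`); Gaussian-windowed ripple bursts placed
#' `swr_lead` seconds before spindle onsets (or independently when no
#' spindles). Ground-truth event tables are returned alongside the
#' signals.
#'
#' @param duration s.
#' @param fs Hz.
#' @param seed RNG seed (generator is a deterministic function of it).
#' @param sw_rate,sw_amp_sd slow-wave rate (1/s) and amplitude in
#'   background-SD units.
#' @param sw_freq slow-wave frequency, Hz (default 1).
#' @param sp_rate,sp_amp_sd,sp_freq,sp_dur spindle rate, amplitude
#'   (SD), carrier frequency and duration.
#' @param phi0_deg,kappa coupling phase (deg; envelope peak on the
#'   slow-wave cosine phase) and von Mises concentration; `NA` phi0
#'   decouples spindles from slow waves.
#' @param swr_rate,swr_amp_sd,swr_freq,swr_dur,swr_lead ripple
#'   parameters; ripples are tied to spindle onsets (lead > 0 places
#'   them before) when spindles exist, else placed independently.
#' @param alpha,noise_sd background spectral exponent and SD.
#' @return list with `lfp` (numeric), `fs`, `truth` (event table),
#'   `meta` (list of all generation parameters).
#' @export
gen_nrem_lfp <- function(duration = 300, fs = 1000, seed = 1,
                         sw_rate = 0.4, sw_amp_sd = 5, sw_freq = 1,
                         sp_rate = 0.2, sp_amp_sd = 6, sp_freq = 12,
                         sp_dur = 1, phi0_deg = 150, kappa = 4,
                         swr_rate = 0.4, swr_amp_sd = 8, swr_freq = 180,
                         swr_dur = 0.06, swr_lead = 0.3,
                         alpha = 1, noise_sd = 1) {
  stopifnot(fs / 2 > swr_freq)
  set.seed(seed)
  n <- round(duration * fs)
  x <- pink_noise(n, fs, alpha, noise_sd)
  tt <- (0:(n - 1)) / fs
  truth <- list()
  add <- function(kind, onset, peak, offset, amplitude)
    events_table(kind = kind, onset = onset, peak = peak,
                 offset = offset, amplitude = amplitude,
                 channel = "synth")
  # slow waves: one cosine cycle, peak then trough
  sw_t <- if (sw_rate > 0)
    place_events(duration, sw_rate, min_gap = 2 / sw_freq) else numeric(0)
  for (s in sw_t) {
    half <- 1 / sw_freq / 2
    idx <- which(tt >= s - half & tt < s + half)
    x[idx] <- x[idx] + sw_amp_sd * noise_sd *
      cos(2 * pi * sw_freq * (tt[idx] - s)) *
      0.5 * (1 + cos(pi * (tt[idx] - s) / half))
  }
  if (length(sw_t))
    truth$sw <- add("slow_wave", sw_t - 1 / sw_freq / 2, sw_t,
                    sw_t + 1 / sw_freq / 2, sw_amp_sd * noise_sd)
  # spindles: envelope peak at slow-wave phase phi0 (phase of the
  # sw_freq cosine centred on the slow-wave peak)
  sp_t <- numeric(0)
  if (sp_rate > 0) {
    if (!is.na(phi0_deg) && length(sw_t)) {
      n_sp <- min(stats::rpois(1, sp_rate * duration), length(sw_t))
      anchors <- sample(sw_t, n_sp)
      dphi <- rvonmises(n_sp, phi0_deg * pi / 180, kappa)
      sp_t <- sort(anchors + dphi / (2 * pi * sw_freq))
    } else {
      sp_t <- place_events(duration, sp_rate, min_gap = 2 * sp_dur)
    }
    sp_t <- sp_t[sp_t > sp_dur & sp_t < duration - sp_dur]
  }
  for (s in sp_t) {
    idx <- which(tt >= s - sp_dur / 2 & tt < s + sp_dur / 2)
    # Hann envelope: its waxing-waning (AC) component is a pure tone at
    # 1/sp_dur Hz, so with sp_dur = 1/sw_freq the envelope rhythm sits
    # exactly at the slow-wave frequency and the coupling phase phi0 is
    # transferred without distortion
    env <- 0.5 * (1 + cos(2 * pi * (tt[idx] - s) / sp_dur))
    x[idx] <- x[idx] + sp_amp_sd * noise_sd * env *
      sin(2 * pi * sp_freq * (tt[idx] - s))
  }
  if (length(sp_t))
    truth$sp <- add("spindle", sp_t - sp_dur / 2, sp_t,
                    sp_t + sp_dur / 2, sp_amp_sd * noise_sd)
  # SWRs
  swr_t <- numeric(0)
  if (swr_rate > 0) {
    if (length(sp_t) && swr_lead > 0) {
      n_swr <- min(stats::rpois(1, swr_rate * duration), length(sp_t))
      swr_t <- sort(sample(sp_t - sp_dur / 2, n_swr)) - swr_lead
    } else {
      swr_t <- place_events(duration, swr_rate, min_gap = 4 * swr_dur)
    }
    swr_t <- swr_t[swr_t > swr_dur & swr_t < duration - swr_dur]
  }
  for (s in swr_t) {
    idx <- which(tt >= s - swr_dur & tt < s + swr_dur)
    x[idx] <- x[idx] + swr_amp_sd * noise_sd *
      exp(-(tt[idx] - s)^2 / (2 * (swr_dur / 4)^2)) *
      sin(2 * pi * swr_freq * (tt[idx] - s))
  }
  if (length(swr_t))
    truth$swr <- add("swr", swr_t - swr_dur, swr_t, swr_t + swr_dur,
                     swr_amp_sd * noise_sd)
  truth <- if (length(truth)) do.call(rbind, truth) else events_table()
  rownames(truth) <- NULL
  list(lfp = x, fs = fs, truth = truth[order(truth$onset_s), ],
       meta = list(seed = seed, duration = duration, fs = fs,
                   sw_rate = sw_rate, sw_amp_sd = sw_amp_sd,
                   sp_rate = sp_rate, sp_amp_sd = sp_amp_sd,
                   phi0_deg = phi0_deg, kappa = kappa,
                   swr_rate = swr_rate, swr_amp_sd = swr_amp_sd,
                   swr_lead = swr_lead, alpha = alpha,
                   noise_sd = noise_sd))
}

#' Generate a staged session with Wake/NREM/REM structure
#'
#' Concatenates state segments with state-dependent spectra: NREM has
#' strong delta (and the NREM event content of [gen_nrem_lfp()]), REM
#' has theta, low EMG and high EOG, Wake has high EMG. The true state
#' sequence is returned as a ground-truth hypnogram.
#'
#' @param states character vector of segment states
#'   (`"Wake"`/`"NREM"`/`"REM"`).
#' @param seg_s segment length, s (multiple of 20 keeps epochs clean).
#' @param fs sampling rate, Hz.
#' @param seed RNG seed.
#' @return list with `mpfc`, `emg`, `eog` signals, `fs`, `truth_bins`
#'   (per-5 s state), `truth` (per-segment data.frame), `events` (NREM
#'   ground-truth events, session time base).
#' @export
gen_session <- function(states = c("Wake", "NREM", "REM", "NREM", "Wake"),
                        seg_s = 120, fs = 250, seed = 1) {
  set.seed(seed)
  nseg <- length(states)
  n <- round(seg_s * fs)
  mpfc <- emg <- eog <- numeric(0)
  events <- list()
  for (k in seq_len(nseg)) {
    st <- states[k]
    seed_k <- seed * 1000 + k
    if (st == "NREM") {
      g <- gen_nrem_lfp(duration = seg_s, fs = fs, seed = seed_k,
                        sw_rate = 0.6, sw_amp_sd = 6, sp_rate = 0.15,
                        swr_rate = 0, swr_freq = min(80, fs / 4))
      seg <- g$lfp
      ev <- g$truth
      if (nrow(ev)) {
        num <- vapply(ev, is.numeric, logical(1))
        num[names(ev) == "amplitude"] <- FALSE
        ev[num] <- ev[num] + (k - 1) * seg_s
        events[[length(events) + 1]] <- ev
      }
      e <- pink_noise(n, fs, 0, 0.3)
      o <- pink_noise(n, fs, 0, 0.3)
    } else if (st == "REM") {
      seg <- pink_noise(n, fs, 1, 1) +
        1.5 * sin(2 * pi * 6 * (0:(n - 1)) / fs +
                    stats::runif(1, 0, 2 * pi))
      e <- pink_noise(n, fs, 0, 0.3)
      o <- pink_noise(n, fs, 0, 2.2)
    } else {
      seg <- pink_noise(n, fs, 1, 1.2)
      e <- pink_noise(n, fs, 0, 2)
      o <- pink_noise(n, fs, 0, 0.6)
    }
    mpfc <- c(mpfc, seg); emg <- c(emg, e); eog <- c(eog, o)
  }
  truth <- data.frame(start_s = (seq_len(nseg) - 1) * seg_s,
                      end_s = seq_len(nseg) * seg_s, label = states,
                      stringsAsFactors = FALSE)
  bins <- data.frame(bin_start_s = seq(0, nseg * seg_s - 5, by = 5))
  bins$label <- states[pmin(nseg, bins$bin_start_s %/% seg_s + 1)]
  list(mpfc = mpfc, emg = emg, eog = eog, fs = fs, truth = truth,
       truth_bins = bins,
       events = if (length(events)) do.call(rbind, events)
                else events_table())
}

#' Generate spikes phase-locked to a rhythm
#'
#' Inhomogeneous Poisson train whose rate is modulated by a von Mises
#' kernel of the reference phase: `rate(t) = rate * exp(kappa *
#' cos(phase(t) - mu)) / I0(kappa)` (unit mean modulation).
#'
#' @param phase reference phase series, radians.
#' @param fs sampling rate of `phase`, Hz.
#' @param mu preferred phase, radians.
#' @param kappa concentration (0 = unmodulated Poisson).
#' @param rate mean firing rate, Hz.
#' @param seed RNG seed.
#' @return spike times, s (relative to the start of `phase`).
#' @export
gen_phase_locked_spikes <- function(phase, fs, mu = 0, kappa = 2,
                                    rate = 5, seed = 1) {
  stopifnot(kappa >= 0)
  set.seed(seed)
  lam <- rate * exp(kappa * cos(phase - mu)) / besselI(kappa, 0)
  p <- pmin(lam / fs, 1)
  which(stats::runif(length(p)) < p) / fs
}

#' Generate evoked intracellular sweeps
#'
#' Logistic-rise EPSP with exponential decay into a hyperpolarizing
#' undershoot, plus Gaussian noise; optional latency jitter across
#' sweeps produces orthodromic-like (jittered) or antidromic-like
#' (fixed-latency) fixtures.
#'
#' @param n_sweeps number of sweeps.
#' @param fs sampling rate, Hz.
#' @param dur_s sweep length, s (stimulus at `stim_time`).
#' @param stim_time stimulus time, s.
#' @param amp_mV,latency_ms,rise_ms EPSP amplitude, 10-percent latency
#'   and logistic rise time-scale.
#' @param hyp_amp_mV,hyp_tau_s hyperpolarization depth and decay.
#' @param jitter_ms SD of the per-sweep latency jitter, ms.
#' @param noise_sd_mV additive noise SD.
#' @param seed RNG seed.
#' @return list with `sweeps` (samples x n_sweeps), `fs`, `stim_time`,
#'   `truth` (list of generation parameters incl. per-sweep latency).
#' @export
gen_evoked_sweeps <- function(n_sweeps = 20, fs = 20000, dur_s = 0.4,
                              stim_time = 0.05, amp_mV = 8,
                              latency_ms = 6, rise_ms = 1.5,
                              hyp_amp_mV = 2, hyp_tau_s = 0.12,
                              jitter_ms = 0, noise_sd_mV = 0.1,
                              seed = 1) {
  set.seed(seed)
  n <- round(dur_s * fs)
  tt <- (0:(n - 1)) / fs
  lat <- latency_ms + stats::rnorm(n_sweeps, 0, jitter_ms)
  sweeps <- matrix(0, n, n_sweeps)
  for (s in seq_len(n_sweeps)) {
    t0 <- stim_time + lat[s] / 1000
    sc <- rise_ms / 1000
    mid <- t0 + sc * log(9)   # so the 10-percent point falls at t0
    rise <- amp_mV / (1 + exp(-(tt - mid) / sc))
    decay <- ifelse(tt > mid + 4 * sc,
                    (amp_mV + hyp_amp_mV) *
                      exp(-(tt - mid - 4 * sc) / hyp_tau_s) - hyp_amp_mV,
                    rise)
    resp <- pmin(rise, decay)
    resp[tt < t0 - 6 * sc] <- 0
    sweeps[, s] <- resp + stats::rnorm(n, 0, noise_sd_mV)
  }
  list(sweeps = sweeps, fs = fs, stim_time = stim_time,
       truth = list(amp_mV = amp_mV, latency_ms = lat,
                    rise_ms = rise_ms, hyp_amp_mV = hyp_amp_mV,
                    hyp_tau_s = hyp_tau_s, jitter_ms = jitter_ms,
                    seed = seed))
}
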