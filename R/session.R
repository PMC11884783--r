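# High-level NREM session analysis of model output: runs the detectors
# on the excitatory membrane potentials and computes the coupling
# statistics of the multi-regional NREM study (lags, synchronization
# index, SWR phase preference, SWR-rate histogram around spindle
# onsets). Shared by the analysis drivers, the acceptance script and
# the acceptance tests.

#' Simulate an NREM session with the calibrated defaults
#'
#' Runs the network for `duration` seconds (including a `burn_in`
#' discard) with the calibrated background-input level
#' (`params$noise.sd`) applied to the cortical and CA3 populations.
#'
#' @param params `somnet_params` (defaults to the shipped calibration).
#' @param duration,burn_in s.
#' @param seed integer seed.
#' @return a `sim_trace`.
#' @export
simulate_nrem_session <- function(params = model_params(),
                                  duration = 1020, burn_in = 20,
                                  seed = 1) {
  simulate_network(params, duration = duration, burn_in = burn_in,
                   seed = seed,
                   noise_sd = params$noise.sd %||% 0)
}

#' NREM event detection and coupling statistics for a model session
#'
#' Detects slow waves (cortical and reuniens membrane potentials),
#' spindles (cortical and reuniens) and SWRs (CA1), then computes:
#' the median reuniens-cortical slow-wave trough lag (within
#' `sw_pair_gap`), the median thalamic-cortical spindle-onset lag
#' (within `sp_pair_gap`, when both spindle sets have at least
#' `min_events` events), the slow-wave/spindle synchronization index
#' per cortical slow wave (cortical and reuniens amplitude), the
#' cortical slow-wave phase at SWR times, and the SWR-rate histogram
#' around cortical spindle onsets. Model reference conventions: the
#' slow-wave anchor is the trough (down state).
#'
#' @param trace a `sim_trace` (or a `recording` with the model
#'   channels).
#' @param min_events minimum event count for lag/rate statistics.
#' @param sw_pair_gap,sp_pair_gap pairing windows, s.
#' @param seed seed for the surrogate shuffles of the rate histogram.
#' @return list of class `nrem_session_stats` with `events` (list of
#'   event tables), `stats` (named list of scalar statistics) and the
#'   underlying result objects.
#' @export
analyze_nrem_session <- function(trace, min_events = 3,
                                 sw_pair_gap = 0.5, sp_pair_gap = 2,
                                 seed = 1) {
  if (inherits(trace, "sim_trace")) {
    fs <- trace$fs
    t0 <- trace$time[1]
    sig <- list(cx = trace$states[, "Ve_CX"],
                reu = trace$states[, "Ve_REU"],
                ca1 = trace$states[, "Ve_CA1"])
  } else if (inherits(trace, "recording")) {
    fs <- trace$fs[["cx"]]
    t0 <- trace$meta$t0 %||% 0
    sig <- trace$signals[c("cx", "reu", "ca1")]
  } else stop("need a sim_trace or recording")
  dur_end <- t0 + length(sig$cx) / fs
  hyp <- hypnogram_all_nrem(dur_end)
  ev <- list(
    sw_cx = detect_slow_waves(sig$cx, fs, hyp, t0 = t0, channel = "cx"),
    sw_re = detect_slow_waves(sig$reu, fs, hyp, t0 = t0, channel = "reu"),
    sp_cx = detect_spindles(sig$cx, fs, hyp, t0 = t0, channel = "cx"),
    sp_re = detect_spindles(sig$reu, fs, hyp, t0 = t0, channel = "reu"),
    swr = detect_swrs(sig$ca1, fs, hyp, t0 = t0, channel = "ca1"))
  st <- list(n_sw_cx = nrow(ev$sw_cx), n_sw_re = nrow(ev$sw_re),
             n_sp_cx = nrow(ev$sp_cx), n_sp_re = nrow(ev$sp_re),
             n_swr = nrow(ev$swr))
  out <- list(events = ev, stats = st)
  # slow-wave trough lag (reuniens relative to cortex; + = reuniens later)
  if (st$n_sw_cx >= min_events && st$n_sw_re >= min_events) {
    pr <- pair_nearest_events(ev$sw_cx, ev$sw_re, max_gap = sw_pair_gap,
                              by = "trough_s")
    out$sw_lag <- pr
    out$stats$sw_trough_lag_s <- pr$median_delay_s
    out$stats$sw_trough_lag_n <- nrow(pr$pairs)
  }
  # spindle onset lag (thalamic relative to cortex; - = thalamus first)
  if (st$n_sp_cx >= min_events && st$n_sp_re >= min_events) {
    pr <- pair_nearest_events(ev$sp_cx, ev$sp_re, max_gap = sp_pair_gap,
                              by = "onset_s")
    out$sp_lag <- pr
    out$stats$sp_onset_lag_s <- pr$median_delay_s
    out$stats$sp_onset_lag_n <- nrow(pr$pairs)
  }
  # slow-wave / spindle synchronization index per cortical slow wave
  if (st$n_sw_cx >= min_events) {
    si_cx <- sw_spindle_coupling(sig$cx, sig$cx, fs, ev$sw_cx,
                                 ref = "trough_s", t0 = t0)
    si_re <- sw_spindle_coupling(sig$cx, sig$reu, fs, ev$sw_cx,
                                 ref = "trough_s", t0 = t0)
    out$si_cx <- si_cx; out$si_re <- si_re
    out$stats$si_strength_cx <- stats::median(si_cx$strength)
    out$stats$si_strength_re <- stats::median(si_re$strength)
    if (nrow(si_cx) >= min_events) {
      cs <- circular_summary(si_cx$angle_deg * pi / 180)
      out$stats$si_angle_cx_deg <- cs$mean_deg
      out$stats$si_angle_cx_p <- cs$p
    }
    if (nrow(si_re) >= min_events) {
      cs <- circular_summary(si_re$angle_deg * pi / 180)
      out$stats$si_angle_re_deg <- cs$mean_deg
      out$stats$si_angle_re_p <- cs$p
    }
  }
  # cortical slow-wave phase at SWR times (0 = slow-wave peak/up state)
  if (st$n_swr >= min_events) {
    ph <- instantaneous_phase(sig$cx, fs, c(0.5, 2))
    idx <- round((ev$swr$peak_s - t0) * fs) + 1
    idx <- idx[idx >= 1 & idx <= length(ph)]
    cs <- circular_summary(ph[idx])
    out$swr_phase <- cs
    out$stats$swr_sw_phase_deg <- cs$mean_deg
    out$stats$swr_sw_phase_p <- cs$p
  }
  # SWR rate around cortical spindle onsets; pre-onset peak lead time
  if (st$n_swr >= min_events && st$n_sp_cx >= min_events) {
    h <- event_rate_histogram(ev$swr, ev$sp_cx, window = 1, bin = 0.1,
                              seed = seed)
    out$swr_rate_hist <- h
    pre <- h$mids < 0
    out$stats$swr_peak_lead_s <- -h$mids[pre][which.max(h$rate[pre])]
  }
  class(out) <- "nrem_session_stats"
  out
}

#' @export
print.nrem_session_stats <- function(x, ...) {
  s <- x$stats
  cat("<nrem_session_stats>\n")
  cat(sprintf("  events: SW %d/%d  spindles %d/%d  SWR %d (cx/reu)\n",
              s$n_sw_cx, s$n_sw_re, s$n_sp_cx, s$n_sp_re, s$n_swr))
  fmt <- function(v, u = "") if (is.null(v)) "n/a" else
    sprintf("%.3f%s", v, u)
  cat("  SW trough lag (reu-cx):", fmt(s$sw_trough_lag_s, " s"), "\n")
  cat("  spindle onset lag:", fmt(s$sp_onset_lag_s, " s"), "\n")
  cat("  |SI| median cx/reu:", fmt(s$si_strength_cx), "/",
      fmt(s$si_strength_re), "\n")
  cat("  SWR slow-wave phase:", fmt(s$swr_sw_phase_deg, " deg"), "\n")
  cat("  SWR rate peak lead:", fmt(s$swr_peak_lead_s, " s"), "\n")
  invisible(x)
}

#' Connectivity sweep over the CA1-reuniens coupling factors
#'
#' Re-runs the NREM session for each pair of scaling factors
#' (`alpha.CA1_REU`, `alpha.REU_CA1`) applied to the two CA1-reuniens
#' E-E pathways and computes, per cell: the peak covariance between the
#' reuniens and CA1 membrane potentials around SWR peaks, the
#' peak-to-trough of the SWR-rate histogram preceding cortical spindle
#' onsets (missing when no spindles are detected), the peak-to-trough
#' of the slow-wave-band CA1 deflection around cortical slow-wave
#' troughs, and the mean slow-wave phase at SWR times (undefined,
#' `NA`, where the Rayleigh test is not significant at `rayleigh_p`).
#'
#' @param params base parameters.
#' @param alpha_ca1_reu,alpha_reu_ca1 grids of scaling factors.
#' @param duration,seed per-cell simulation settings.
#' @param rayleigh_p significance gate for the phase metric.
#' @return data.frame, one row per grid cell, with the metric columns
#'   (`NA` = undefined / insufficient events).
#' @export
run_connectivity_sweep <- function(params = model_params(),
                                   alpha_ca1_reu = c(0.5, 1, 2),
                                   alpha_reu_ca1 = c(0.5, 1, 2),
                                   duration = 220, seed = 1,
                                   rayleigh_p = 0.05) {
  grid <- expand.grid(alpha_ca1_reu = alpha_ca1_reu,
                      alpha_reu_ca1 = alpha_reu_ca1)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$alpha.CA1_REU <- grid$alpha_ca1_reu[i]
    p$alpha.REU_CA1 <- grid$alpha_reu_ca1[i]
    tr <- simulate_nrem_session(p, duration = duration, seed = seed)
    an <- analyze_nrem_session(tr, seed = seed)
    fs <- tr$fs; t0 <- tr$time[1]
    reu <- tr$states[, "Ve_REU"]; ca1 <- tr$states[, "Ve_CA1"]
    cx <- tr$states[, "Ve_CX"]
    # SWR-locked reuniens-CA1 covariance peak (+/- 0.5 s around peaks)
    cov_pk <- NA_real_
    if (nrow(an$events$swr) >= 5) {
      w <- round(0.5 * fs)
      segs <- lapply(an$events$swr$peak_s, function(tt) {
        i0 <- round((tt - t0) * fs) + 1
        if (i0 - w < 1 || i0 + w > length(reu)) return(NULL)
        cbind(reu[(i0 - w):(i0 + w)], ca1[(i0 - w):(i0 + w)])
      })
      segs <- Filter(Negate(is.null), segs)
      if (length(segs) >= 5) {
        r_mat <- sapply(segs, function(s) s[, 1])
        c_mat <- sapply(segs, function(s) s[, 2])
        # covariance across events at each lag pair collapsed to the
        # maximal same-time covariance across the window
        cov_t <- vapply(seq_len(nrow(r_mat)), function(k)
          stats::cov(r_mat[k, ], c_mat[k, ]), numeric(1))
        cov_pk <- max(cov_t)
      }
    }
    # pre-spindle SWR rate peak-to-trough (window -1..0 s)
    swr_p2t <- NA_real_
    if (!is.null(an$swr_rate_hist)) {
      pre <- an$swr_rate_hist$mids < 0
      swr_p2t <- diff(range(an$swr_rate_hist$rate[pre]))
    }
    # CA1 slow-wave-band deflection p2p around cortical SW troughs
    ca1_p2t <- NA_real_
    if (nrow(an$events$sw_cx) >= 5) {
      ca1_sw <- bandpass_fir(ca1, fs, c(0.5, 2))
      w <- round(1 * fs)
      segs <- lapply(an$events$sw_cx$trough_s, function(tt) {
        i0 <- round((tt - t0) * fs) + 1
        if (i0 - w < 1 || i0 + w > length(ca1_sw)) return(NULL)
        ca1_sw[(i0 - w):(i0 + w)]
      })
      segs <- Filter(Negate(is.null), segs)
      if (length(segs) >= 5) {
        avg <- rowMeans(do.call(cbind, segs))
        ca1_p2t <- diff(range(avg))
      }
    }
    ph <- an$stats$swr_sw_phase_deg
    if (is.null(ph) || is.null(an$stats$swr_sw_phase_p) ||
        an$stats$swr_sw_phase_p >= rayleigh_p) ph <- NA_real_
    data.frame(alpha_ca1_reu = grid$alpha_ca1_reu[i],
               alpha_reu_ca1 = grid$alpha_reu_ca1[i],
               swr_reu_cov_peak = cov_pk,
               pre_spindle_swr_p2t = swr_p2t,
               ca1_sw_deflection_p2t = ca1_p2t,
               sw_phase_at_swr_deg = ph,
               n_swr = nrow(an$events$swr),
               n_sw = nrow(an$events$sw_cx))
  })
  do.call(rbind, res)
}
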