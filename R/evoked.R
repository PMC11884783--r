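# Quantification of evoked intracellular responses: EPSP latency,
# amplitude and slope from a sigmoid fit of the rising phase, duration
# of the late hyperpolarization, orthodromic/antidromic classification
# by latency jitter, and normalization of 5-pulse train responses.

#' Characterize an evoked EPSP from a single (or averaged) sweep
#'
#' A 4-parameter logistic is fitted to the rising phase of the response
#' (from onset, found by a derivative threshold, to the peak). Latency
#' is the time at which the fit reaches 10 percent of its amplitude
#' above baseline; amplitude is the fitted maximum minus baseline;
#' slope is the maximum of the fitted derivative (`A / (4 * scale)`).
#' The hyperpolarization duration is the span for which the post-EPSP
#' trace stays below a horizontal line at the EPSP base (the fitted
#' lower asymptote).
#'
#' @param sweep membrane potential, mV.
#' @param fs sampling rate, Hz.
#' @param stim_time stimulus time within the sweep, s.
#' @param baseline_s pre-stimulus baseline span, s (default 0.02).
#' @param min_snr response threshold: peak must exceed `min_snr` times
#'   the baseline SD (default 3).
#' @param search_s post-stimulus window searched for the EPSP peak, s.
#' @return list of class `evoked_metrics`: `latency_ms`,
#'   `amplitude_mV`, `slope_V_per_s`, `hyperpol_ms`, `response`
#'   (`"epsp"` or `"none"`), `fit` (the nls object or NULL).
#' @export
characterize_epsp <- function(sweep, fs, stim_time, baseline_s = 0.02,
                              min_snr = 3, search_s = 0.05) {
  i_stim <- round(stim_time * fs) + 1L
  ib <- max(1L, i_stim - round(baseline_s * fs)):max(1L, i_stim - 1L)
  base_mu <- mean(sweep[ib]); base_sd <- stats::sd(sweep[ib])
  none <- list(latency_ms = NA_real_, amplitude_mV = NA_real_,
               slope_V_per_s = NA_real_, hyperpol_ms = NA_real_,
               response = "none", fit = NULL)
  class(none) <- "evoked_metrics"
  i_end <- min(length(sweep), i_stim + round(search_s * fs))
  seg <- sweep[i_stim:i_end]
  ipk <- which.max(seg)
  if (base_sd == 0) base_sd <- 1e-9
  if (seg[ipk] - base_mu < min_snr * base_sd) return(none)
  # onset: last sample before the derivative first exceeds 10 percent
  # of its maximum within the rise
  d <- c(0, diff(seg[1:ipk]))
  thr_d <- 0.1 * max(d)
  r0 <- which(d >= thr_d)[1]
  i_on <- max(r0 - 1L, 1L)
  tt <- (seq(i_on, ipk) - 1) / fs
  yy <- seg[i_on:ipk]
  if (length(tt) < 5) return(none)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ lo + A / (1 + exp(-(tt - mid) / sc)),
      start = list(lo = min(yy), A = diff(range(yy)),
                   mid = mean(range(tt)), sc = diff(range(tt)) / 6),
      lower = c(-Inf, 1e-9, min(tt) - diff(range(tt)),
                diff(range(tt)) / 1e4),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(none)
  cf <- stats::coef(fit)
  A <- cf[["A"]]; mid <- cf[["mid"]]; sc <- cf[["sc"]]; lo <- cf[["lo"]]
  # time at 10 percent of the fitted maximum amplitude: lo + 0.1 A
  t10 <- mid - sc * log(9)   # stimulus-relative (tt grid starts at stim)
  latency_ms <- t10 * 1000
  slope <- A / (4 * sc) / 1000  # mV/s -> V/s
  # hyperpolarization: from first post-peak crossing below the EPSP
  # base until recovery above it
  base_line <- lo
  post <- sweep[(i_stim + ipk - 1):length(sweep)]
  below <- which(post < base_line)
  hyp_ms <- if (length(below)) {
    b0 <- below[1]
    rec <- which(post[b0:length(post)] >= base_line)
    ((if (length(rec)) rec[1] - 1 else length(post) - b0 + 1) / fs) * 1000
  } else NA_real_
  out <- list(latency_ms = latency_ms, amplitude_mV = A,
              slope_V_per_s = slope, hyperpol_ms = hyp_ms,
              response = "epsp", fit = fit)
  class(out) <- "evoked_metrics"
  out
}

#' @export
print.evoked_metrics <- function(x, ...) {
  if (x$response == "none") cat("<evoked_metrics> no response\n")
  else cat(sprintf(
    "<evoked_metrics> latency %.2f ms, amplitude %.2f mV, slope %.2f V/s, hyperpol %.0f ms\n",
    x$latency_ms, x$amplitude_mV, x$slope_V_per_s, x$hyperpol_ms))
  invisible(x)
}

#' Classify evoked spikes as orthodromic or antidromic by latency jitter
#'
#' Antidromic spikes have near-constant latency; orthodromic (synaptic)
#' spikes jitter. Latency SD at or below `jitter_thr_ms` classifies
#' antidromic, above orthodromic. When the latencies form two clusters
#' (separated by > `bimodal_gap_ms`) with one low-jitter mode, the
#' response is `"both"`.
#'
#' @param latencies_ms spike latencies across repeated stimuli, ms.
#' @param jitter_thr_ms antidromic jitter threshold, ms (default 0.3).
#' @param bimodal_gap_ms minimal separation of two latency modes, ms.
#' @return `"antidromic"`, `"orthodromic"`, `"both"` or
#'   `"unclassified"` (fewer than 5 responses).
#' @export
classify_spike_response <- function(latencies_ms, jitter_thr_ms = 0.3,
                                    bimodal_gap_ms = 2) {
  lat <- latencies_ms[is.finite(latencies_ms)]
  if (length(lat) < 5) return("unclassified")
  km <- suppressWarnings(stats::kmeans(lat, centers = 2, nstart = 5))
  gap <- abs(diff(sort(km$centers)))
  if (gap > bimodal_gap_ms && min(table(km$cluster)) >= 3) {
    sds <- tapply(lat, km$cluster, stats::sd)
    tight <- sds <= jitter_thr_ms
    if (any(tight) && !all(tight)) return("both")
  }
  if (stats::sd(lat) <= jitter_thr_ms) "antidromic" else "orthodromic"
}

#' Normalize responses to 5-pulse stimulus trains
#'
#' Computes, per pulse, the area between the sweep and the pre-pulse
#' baseline over a response window, averaged across sweeps, and divides
#' the areas of pulses 2..n by the pulse-1 area. Sweeps whose pulse-1
#' area is not positive are excluded.
#'
#' @param sweeps matrix (samples x sweeps) of membrane potential.
#' @param fs sampling rate, Hz.
#' @param pulse_times pulse onset times within a sweep, s.
#' @param resp_s response integration window after each pulse, s.
#' @param baseline_s pre-pulse baseline span, s.
#' @return list with `areas` (pulse x sweep matrix), `mean_areas`,
#'   `normalized` (pulses relative to pulse 1), `n_used`.
#' @export
normalize_train_responses <- function(sweeps, fs, pulse_times,
                                      resp_s = NULL, baseline_s = 0.005) {
  if (is.vector(sweeps)) sweeps <- matrix(sweeps, ncol = 1)
  np <- length(pulse_times)
  if (np < 2) stop("need at least 2 pulses")
  if (is.null(resp_s)) resp_s <- min(diff(pulse_times)) * 0.9
  areas <- matrix(NA_real_, np, ncol(sweeps))
  for (s in seq_len(ncol(sweeps))) {
    for (p in seq_len(np)) {
      i0 <- round(pulse_times[p] * fs) + 1L
      ib <- max(1L, i0 - round(baseline_s * fs)):max(1L, i0 - 1L)
      i1 <- min(nrow(sweeps), i0 + round(resp_s * fs))
      areas[p, s] <- sum(sweeps[i0:i1, s] - mean(sweeps[ib, s])) / fs
    }
  }
  used <- which(areas[1, ] > 0)
  if (!length(used)) stop("no sweep with positive pulse-1 area")
  mean_areas <- rowMeans(areas[, used, drop = FALSE])
  list(areas = areas, mean_areas = mean_areas,
       normalized = mean_areas / mean_areas[1], n_used = length(used))
}
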