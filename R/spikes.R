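# Spike detection with artifact rejection, PCA+GMM unit sorting,
# surrogate-normalized peri-event histograms and spike-LFP phase
# locking.

#' Reject high-amplitude artifacts
#'
#' Masks epochs of +/- `pad_s` around samples where the signal crosses
#' +/- `thr_sd` SDs; overlapping intervals are merged.
#'
#' @param x signal (typically 300-8000 Hz bandpassed).
#' @param fs sampling rate, Hz.
#' @param thr_sd threshold in SD units (default 16).
#' @param pad_s half-width of the exclusion window, s (default 0.25).
#' @return list with `mask` (logical, TRUE = usable) and `intervals`
#'   (data.frame start_s, end_s of exclusions).
#' @export
reject_artifacts <- function(x, fs, thr_sd = 16, pad_s = 0.25) {
  s <- stats::sd(x)
  bad <- which(abs(x) > thr_sd * s)
  mask <- rep(TRUE, length(x))
  if (!length(bad))
    return(list(mask = mask,
                intervals = data.frame(start_s = numeric(),
                                       end_s = numeric())))
  pad <- round(pad_s * fs)
  a <- pmax(bad - pad, 1L); b <- pmin(bad + pad, length(x))
  o <- order(a); a <- a[o]; b <- b[o]
  ms <- list(); ca <- a[1]; cb <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] <= cb + 1L) cb <- max(cb, b[i])
    else { ms[[length(ms) + 1]] <- c(ca, cb); ca <- a[i]; cb <- b[i] }
  }
  ms[[length(ms) + 1]] <- c(ca, cb)
  m <- do.call(rbind, ms)
  for (i in seq_len(nrow(m))) mask[m[i, 1]:m[i, 2]] <- FALSE
  list(mask = mask,
       intervals = data.frame(start_s = (m[, 1] - 1) / fs,
                              end_s = m[, 2] / fs))
}

#' Detect spikes by negative threshold crossing
#'
#' Negative threshold at `-thr_sd` robust SDs (median absolute
#' deviation / 0.6745, resistant to spike contamination); a shadow
#' period after each crossing suppresses multiple detections of one
#' event; waveform snippets cover 0.6 ms before to 0.9 ms after the
#' crossing; spike time is the trough within the snippet window.
#'
#' @param x bandpassed signal, or a matrix (samples x channels) for
#'   multichannel (e.g. tetrode) data; detection runs on the channel
#'   with the largest robust SD and snippets are cut on all channels.
#' @param fs sampling rate, Hz (at least 20 kHz for the stated snippet
#'   resolution).
#' @param thr_sd threshold in robust SD units (default 4).
#' @param shadow_s shadow period, s (default 0.75 ms).
#' @param snip_pre_s,snip_post_s snippet window, s.
#' @param mask optional logical vector from [reject_artifacts()].
#' @return list of class `spike_train`: `times` (s), `snippets` (array
#'   spikes x samples x channels), `fs`, `unit` (NA before sorting),
#'   `threshold` used.
#' @export
detect_spikes <- function(x, fs, thr_sd = 4, shadow_s = 0.00075,
                          snip_pre_s = 0.0006, snip_post_s = 0.0009,
                          mask = NULL) {
  if (fs < 20000)
    stop("sampling rate too low for 1.5 ms snippets at stated precision")
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (is.null(mask)) mask <- rep(TRUE, n)
  rsd <- apply(x, 2, function(ch) stats::median(abs(ch)) / 0.6745)
  dch <- which.max(rsd)
  thr <- -thr_sd * rsd[dch]
  xi <- x[, dch]
  cross <- which(xi[-1] < thr & xi[-n] >= thr) + 1L
  cross <- cross[mask[cross]]
  pre <- round(snip_pre_s * fs); post <- round(snip_post_s * fs)
  shadow <- round(shadow_s * fs)
  keep <- integer(0); last <- -Inf
  for (i in cross) {
    if (i - last > shadow) { keep <- c(keep, i); last <- i }
  }
  keep <- keep[keep - pre >= 1 & keep + post <= n]
  if (length(keep)) {
    ok <- vapply(keep, function(i) all(mask[(i - pre):(i + post)]),
                 logical(1))
    keep <- keep[ok]
  }
  nsnip <- pre + post + 1L
  snips <- array(NA_real_, c(length(keep), nsnip, ncol(x)))
  times <- numeric(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    seg <- x[(i - pre):(i + post), , drop = FALSE]
    snips[k, , ] <- seg
    times[k] <- (i - 1 + (which.min(seg[, dch]) - 1 - pre)) / fs
  }
  structure(list(times = times, snippets = snips, fs = fs,
                 unit = rep(NA_integer_, length(times)),
                 threshold = thr, det_channel = dch),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes, %d channel(s), fs = %g Hz\n",
              length(x$times), dim(x$snippets)[3], x$fs))
  invisible(x)
}

#' Sort spikes into units by waveform features
#'
#' Per channel, three features per spike: peak-to-trough amplitude,
#' trough value and an indicator that the channel carries the maximal
#' trough. PCA combines the features; a Gaussian mixture model
#' (components selected by BIC over `1:max_units`) on the first two
#' components assigns units; spikes whose Mahalanobis distance from
#' their cluster center exceeds `mahal_max` are dropped (unit NA).
#'
#' @param train a `spike_train`.
#' @param max_units maximum number of mixture components (default 5).
#' @param mahal_max Mahalanobis pruning radius (default 4; `Inf` keeps
#'   all spikes).
#' @return the train with `unit` filled in and attribute `"sorting"`
#'   (list with the PCA scores and the fitted model).
#' @importFrom mclust Mclust mclustBIC
#' @export
sort_units <- function(train, max_units = 5, mahal_max = 4) {
  ns <- length(train$times)
  nch <- dim(train$snippets)[3]
  if (ns < 10) {
    warning("too few spikes to sort; assigning single unit")
    train$unit <- rep(1L, ns)
    return(train)
  }
  troughs <- apply(train$snippets, c(1, 3), min)
  peaks <- apply(train$snippets, c(1, 3), max)
  maxch <- apply(-troughs, 1, which.max)
  ind <- matrix(0, ns, nch)
  ind[cbind(seq_len(ns), maxch)] <- 1
  feats <- cbind(peaks - troughs, troughs, ind)
  keepc <- apply(feats, 2, stats::sd) > 0
  pc <- stats::prcomp(feats[, keepc, drop = FALSE], scale. = TRUE)
  sc <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  bic <- mclust::mclustBIC(sc, G = 1:max_units, verbose = FALSE)
  fit <- mclust::Mclust(sc, x = bic, verbose = FALSE)
  cl <- fit$classification
  # Mahalanobis pruning per cluster
  unit <- as.integer(cl)
  for (g in unique(cl)) {
    i <- which(cl == g)
    if (length(i) < 4) next
    mu <- colMeans(sc[i, , drop = FALSE])
    S <- stats::cov(sc[i, , drop = FALSE])
    if (det(S) <= 0) next
    d2 <- stats::mahalanobis(sc[i, , drop = FALSE], mu, S)
    unit[i][sqrt(d2) > mahal_max] <- NA_integer_
  }
  train$unit <- unit
  attr(train, "sorting") <- list(scores = sc, model = fit)
  train
}

#' Peri-event time histogram with surrogate z-normalization
#'
#' Spike rate around event onsets in `bin_s` bins over `+/- window_s`,
#' smoothed with a Gaussian kernel of SD `smooth_s`. Surrogate PETHs shuffle each
#' event time uniformly within `+/- shuffle_window_s` (seeded, repeated
#' `n_shuffles` times); the observed PETH is z-scored against them. A
#' unit is `activated` when any z in the `(0, class_window_s]`
#' post-onset window exceeds `z_thr`, `suppressed` when any falls below
#' `-z_thr`, else `unmodulated`.
#'
#' @param spike_times spike times, s.
#' @param event_times event (reference) times, s.
#' @param window_s half-window, s (default 0.5).
#' @param bin_s bin width, s (default 0.01).
#' @param smooth_s Gaussian smoothing window, s (default 0.01).
#' @param n_shuffles number of surrogates (default 100).
#' @param shuffle_window_s half-width of the event jitter, s (0.5 so
#'   events move within a 1 s window).
#' @param class_window_s post-onset classification window, s (0.15).
#' @param z_thr classification threshold (default 2).
#' @param seed RNG seed.
#' @return list of class `peth`: `mids`, `rate`, `z`, `surrogate_mean`,
#'   `surrogate_sd`, `classification`.
#' @export
peth_zscore <- function(spike_times, event_times, window_s = 0.5,
                        bin_s = 0.01, smooth_s = 0.01, n_shuffles = 100,
                        shuffle_window_s = 0.5, class_window_s = 0.15,
                        z_thr = 2, seed = 1) {
  stopifnot(length(spike_times) > 0, length(event_times) > 0)
  breaks <- seq(-window_s, window_s, by = bin_s)
  mids <- breaks[-1] - bin_s / 2
  fsb <- 1 / bin_s
  one <- function(ev) {
    rel <- unlist(lapply(ev, function(e) {
      d <- spike_times - e
      d[d >= -window_s & d < window_s]
    }))
    counts <- if (length(rel))
      graphics::hist(rel, breaks = breaks, plot = FALSE)$counts
    else numeric(length(mids))
    gaussian_smooth(counts / (length(ev) * bin_s), fsb, smooth_s * 6)
  }
  obs <- one(event_times)
  if (!is.null(seed)) set.seed(seed)
  sur <- replicate(n_shuffles,
    one(event_times + stats::runif(length(event_times),
                                   -shuffle_window_s, shuffle_window_s)))
  mu <- rowMeans(sur); sdev <- apply(sur, 1, stats::sd)
  z <- ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
  w <- mids > 0 & mids <= class_window_s
  zw <- z[w]; zw <- zw[is.finite(zw)]
  cls <- if (!length(zw)) "unmodulated"
  else if (any(zw > z_thr)) "activated"
  else if (any(zw < -z_thr)) "suppressed"
  else "unmodulated"
  structure(list(mids = mids, rate = obs, z = z, surrogate_mean = mu,
                 surrogate_sd = sdev, classification = cls),
            class = "peth")
}

#' Spike-LFP phase locking
#'
#' Samples a reference-rhythm phase series at spike times falling
#' within `+/- gate_s` of any gating event time, and returns circular
#' summary statistics. With fewer than `min_spikes` gated spikes the
#' result is flagged and no p-value is computed.
#'
#' @param spike_times spike times, s.
#' @param phase phase series (radians) sampled at `fs`.
#' @param fs sampling rate of `phase`, Hz.
#' @param gate_times event times gating the analysis, s (`NULL` = no
#'   gate).
#' @param gate_s half-width of the gate, s.
#' @param min_spikes minimum gated spikes (default 10).
#' @param t0 time of the first phase sample, s.
#' @return list with `n`, `phases` (radians), and (when `n >=
#'   min_spikes`) the [circular_summary()] fields; otherwise
#'   `flagged = TRUE`.
#' @export
spike_phase_locking <- function(spike_times, phase, fs, gate_times = NULL,
                                gate_s = 0.25, min_spikes = 10, t0 = 0) {
  st <- spike_times
  if (!is.null(gate_times) && length(gate_times)) {
    ok <- vapply(st, function(s) any(abs(gate_times - s) <= gate_s),
                 logical(1))
    st <- st[ok]
  }
  idx <- round((st - t0) * fs) + 1L
  idx <- idx[idx >= 1 & idx <= length(phase)]
  ph <- phase[idx]
  if (length(ph) < min_spikes)
    return(list(n = length(ph), phases = ph, flagged = TRUE))
  c(list(phases = ph, flagged = FALSE), circular_summary(ph))
}
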