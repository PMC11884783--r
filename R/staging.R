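# Automated Wake/NREM/REM staging from mPFC, EMG and EOG signals:
# 5 s bins of squared (optionally delta-filtered) signals, per-session
# mean/SD thresholds, then 20 s majority epochs.

#' Stage 5-second bins from mPFC, EMG and EOG signals
#'
#' The mPFC signal is downsampled to 100 Hz and bandpassed in the delta
#' range (1-4 Hz); the mPFC, delta and EMG (and EOG) signals are
#' squared and averaged in 5 s bins. A bin is NREM when the mPFC and
#' delta bins exceed their session `mean + 1 SD` and the EMG bin falls
#' below `mean - 1 SD`; all other bins start as Wake; Wake bins with
#' EMG below `mean - 1 SD` and EOG above `mean + 1 SD` are relabelled
#' REM. Without an EOG channel the REM rule is skipped with a warning.
#'
#' @param mpfc,emg,eog signals (same duration; `eog` may be `NULL`).
#' @param fs sampling rate of all three, Hz (at least 100).
#' @param bin_s bin length, s (default 5).
#' @return object of class `staging_bins`: data.frame with bin times,
#'   bin means and `label`.
#' @export
stage_bins <- function(mpfc, emg, eog = NULL, fs, bin_s = 5) {
  stopifnot(fs >= 100)
  if (length(mpfc) < 60 * fs) stop("need at least 60 s of signal")
  dec <- max(1L, round(fs / 100))
  fs_d <- fs / dec
  mp <- mpfc[seq(1, length(mpfc), by = dec)]
  delta <- bandpass_fir(mp, fs_d, c(1, 4))
  binmean <- function(x, fs_x) {
    nb <- floor(length(x) / (bin_s * fs_x))
    idx <- rep(seq_len(nb), each = round(bin_s * fs_x))[seq_len(length(x))]
    as.numeric(tapply(x^2, idx[seq_along(x)], mean)[seq_len(nb)])
  }
  b_mp <- binmean(mp, fs_d)
  b_de <- binmean(delta, fs_d)
  b_em <- binmean(emg, fs)
  nb <- min(length(b_mp), length(b_de), length(b_em))
  b_eo <- if (!is.null(eog)) binmean(eog, fs) else NULL
  if (!is.null(b_eo)) nb <- min(nb, length(b_eo))
  b_mp <- b_mp[1:nb]; b_de <- b_de[1:nb]; b_em <- b_em[1:nb]
  if (!is.null(b_eo)) b_eo <- b_eo[1:nb]
  zchk <- function(x, nm) if (stats::sd(x) == 0)
    stop("zero-variance channel: ", nm)
  zchk(b_mp, "mpfc"); zchk(b_de, "delta"); zchk(b_em, "emg")
  thr <- function(x) c(mean(x), stats::sd(x))
  tm <- thr(b_mp); td <- thr(b_de); te <- thr(b_em)
  lab <- ifelse(b_mp > tm[1] + tm[2] & b_de > td[1] + td[2] &
                  b_em < te[1] - te[2], "NREM", "Wake")
  if (!is.null(b_eo)) {
    zchk(b_eo, "eog")
    to <- thr(b_eo)
    rem <- lab == "Wake" & b_em < te[1] - te[2] & b_eo > to[1] + to[2]
    lab[rem] <- "REM"
  } else {
    warning("no EOG channel: REM rule skipped")
  }
  out <- data.frame(bin_start_s = (seq_len(nb) - 1) * bin_s,
                    bin_end_s = seq_len(nb) * bin_s,
                    mpfc = b_mp, delta = b_de, emg = b_em,
                    eog = if (is.null(b_eo)) NA_real_ else b_eo,
                    label = lab, stringsAsFactors = FALSE)
  class(out) <- c("staging_bins", class(out))
  out
}

#' Build a hypnogram from staged bins
#'
#' Groups of 4 consecutive 5 s bins form 20 s epochs labelled by
#' majority; epochs without a majority label are `"Transition"`. A
#' trailing partial epoch is dropped with a warning.
#'
#' @param bins a `staging_bins` data.frame from [stage_bins()].
#' @param group number of bins per epoch (default 4).
#' @return hypnogram `data.frame` (epoch_start_s, epoch_end_s, label)
#'   with the bin table in attribute `"bins"`.
#' @export
build_hypnogram <- function(bins, group = 4) {
  nb <- nrow(bins)
  nep <- nb %/% group
  if (nb %% group != 0)
    warning("dropping trailing partial epoch (", nb %% group, " bins)")
  lab <- vapply(seq_len(nep), function(i) {
    g <- bins$label[((i - 1) * group + 1):(i * group)]
    tab <- sort(table(g), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "Transition"
    else if (tab[1] > group / 2) names(tab)[1]
    else "Transition"
  }, character(1))
  hyp <- data.frame(
    epoch_start_s = (seq_len(nep) - 1) * group * (bins$bin_end_s[1] -
                                                    bins$bin_start_s[1]),
    epoch_end_s = seq_len(nep) * group * (bins$bin_end_s[1] -
                                            bins$bin_start_s[1]),
    label = lab, stringsAsFactors = FALSE)
  attr(hyp, "bins") <- bins
  hyp
}
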