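# Event detectors against constructions with known ground truth.

test_that("one injected slow wave in noise is detected exactly once", {
  fs <- 500
  set.seed(2)
  dur <- 120
  n <- dur * fs
  x <- bandpass_fir(pink_noise(n, fs, 1, 1), fs, c(6, 40))
  tt <- (0:(n - 1)) / fs
  # one biphasic 1 Hz wave, huge against the near-empty slow band
  ctr <- 60
  idx <- which(tt >= ctr - 0.5 & tt < ctr + 0.5)
  x[idx] <- x[idx] + 5 * cos(2 * pi * (tt[idx] - ctr)) *
    0.5 * (1 + cos(pi * (tt[idx] - ctr) / 0.5))
  hyp <- hypnogram_all_nrem(dur)
  ev <- detect_slow_waves(x, fs, hyp)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$peak_s - ctr), 0.15)
  expect_true(ev$onset_s <= ev$peak_s && ev$peak_s <= ev$offset_s)
  expect_true(ev$trough_s >= ev$onset_s && ev$trough_s <= ev$offset_s)
})

test_that("slow-wave counts are monotone in the peak threshold", {
  fs <- 500
  set.seed(3)
  x <- pink_noise(90 * fs, fs, 1, 1)
  hyp <- hypnogram_all_nrem(90)
  n_low <- nrow(detect_slow_waves(x, fs, hyp, peak_sd = 1, p2p_sd = 1.5))
  n_high <- nrow(detect_slow_waves(x, fs, hyp, peak_sd = 2, p2p_sd = 3))
  expect_lte(n_high, n_low)
})

test_that("a slow 0.2 Hz wave is rejected by the zero-crossing rule", {
  fs <- 500
  set.seed(4)
  dur <- 120
  n <- dur * fs
  x <- bandpass_fir(pink_noise(n, fs, 1, 0.5), fs, c(6, 40))
  tt <- (0:(n - 1)) / fs
  ctr <- 60
  idx <- which(tt >= ctr - 2.5 & tt < ctr + 2.5)
  x[idx] <- x[idx] + 6 * cos(2 * pi * 0.2 * (tt[idx] - ctr)) *
    0.5 * (1 + cos(pi * (tt[idx] - ctr) / 2.5))
  ev <- detect_slow_waves(x, fs, hypnogram_all_nrem(dur))
  expect_true(nrow(ev) == 0 || all(abs(ev$peak_s - ctr) > 1))
})

test_that("spindle detection recovers an injected burst with onset/offset accuracy", {
  fs <- 500
  set.seed(5)
  dur <- 180
  n <- dur * fs
  x <- pink_noise(n, fs, 1, 1)
  tt <- (0:(n - 1)) / fs
  ctr <- 90
  idx <- which(tt >= ctr - 0.5 & tt < ctr + 0.5)
  x[idx] <- x[idx] + 6 * sin(2 * pi * 12 * (tt[idx] - ctr)) *
    0.5 * (1 + cos(2 * pi * (tt[idx] - ctr)))
  ev <- detect_spindles(x, fs, hypnogram_all_nrem(dur))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_s - (ctr - 0.5)), 0.12)
  expect_lt(abs(ev$offset_s - (ctr + 0.5)), 0.12)
  dur_ev <- ev$offset_s - ev$onset_s
  expect_true(dur_ev >= 0.5 && dur_ev <= 3)
})

test_that("two nearby bursts merge and short bursts are dropped", {
  fs <- 500
  set.seed(6)
  dur <- 180
  n <- dur * fs
  x <- pink_noise(n, fs, 1, 1)
  tt <- (0:(n - 1)) / fs
  burst <- function(ctr, len, amp = 6) {
    idx <- which(tt >= ctr - len / 2 & tt < ctr + len / 2)
    x[idx] <<- x[idx] + amp * sin(2 * pi * 12 * (tt[idx] - ctr)) *
      0.5 * (1 + cos(2 * pi * (tt[idx] - ctr) / len))
  }
  # two 0.7 s bursts separated by a 0.3 s gap -> one merged event
  burst(60 - 0.5, 0.7); burst(60 + 0.5, 0.7)
  # a lone 0.3 s burst -> below the duration gate
  burst(120, 0.3)
  ev <- detect_spindles(x, fs, hypnogram_all_nrem(dur))
  near60 <- ev[abs(ev$peak_s - 60) < 2, ]
  near120 <- ev[abs(ev$peak_s - 120) < 2, ]
  expect_equal(nrow(near60), 1)
  expect_equal(nrow(near120), 0)
})

test_that("SWR detection requires 30 ms above threshold", {
  fs <- 1000
  set.seed(7)
  dur <- 120
  n <- dur * fs
  x <- pink_noise(n, fs, 1, 1)
  tt <- (0:(n - 1)) / fs
  rip <- function(ctr, len, amp = 8) {
    idx <- which(tt >= ctr - len & tt < ctr + len)
    x[idx] <<- x[idx] + amp *
      exp(-(tt[idx] - ctr)^2 / (2 * (len / 2)^2)) *
      sin(2 * pi * 180 * (tt[idx] - ctr))
  }
  rip(40, 0.05)        # 100 ms envelope: detectable
  rip(80, 0.005, amp = 3)  # ~10 ms, weak: too short
  ev <- detect_swrs(x, fs, hypnogram_all_nrem(dur))
  expect_equal(sum(abs(ev$peak_s - 40) < 0.1), 1)
  expect_equal(sum(abs(ev$peak_s - 80) < 0.1), 0)
  expect_error(detect_swrs(x, 400, hypnogram_all_nrem(dur)), "too low")
})

test_that("detectors are confined to NREM and empty without it", {
  fs <- 500
  set.seed(8)
  x <- pink_noise(60 * fs, fs, 1, 1)
  hyp_w <- data.frame(epoch_start_s = 0, epoch_end_s = 60, label = "Wake")
  expect_warning(ev <- detect_spindles(x, fs, hyp_w), "no NREM")
  expect_equal(nrow(ev), 0)
  # flat signal inside NREM errors on zero variance
  expect_error(detect_spindles(rep(0, 60 * fs), fs,
                               hypnogram_all_nrem(60)), "zero-variance")
})

test_that("detector sensitivity and false-positive rate meet the targets on the SNR-6 fixture", {
  fs <- 1000
  g <- gen_nrem_lfp(duration = 400, fs = fs, seed = 11,
                    sw_rate = 0.25, sw_amp_sd = 6,
                    sp_rate = 0.12, sp_amp_sd = 6, sp_dur = 1.8,
                    phi0_deg = NA,
                    swr_rate = 0.15, swr_amp_sd = 6, swr_lead = 0)
  hyp <- hypnogram_all_nrem(400)
  dur_eff <- 400
  truth <- g$truth
  score <- function(ev, kind, tol) {
    tr <- truth[truth$kind == kind, ]
    hit <- vapply(tr$peak_s, function(s)
      any(abs(ev$peak_s - s) < tol), logical(1))
    fp <- vapply(ev$peak_s, function(s)
      all(abs(tr$peak_s - s) > tol), logical(1))
    c(sens = mean(hit), fprate = sum(fp) / dur_eff)
  }
  sw <- score(detect_slow_waves(g$lfp, fs, hyp), "slow_wave", 0.4)
  sp <- score(detect_spindles(g$lfp, fs, hyp), "spindle", 0.6)
  rp <- score(detect_swrs(g$lfp, fs, hyp), "swr", 0.2)
  expect_gte(sw["sens"], 0.95)
  expect_gte(sp["sens"], 0.95)
  expect_gte(rp["sens"], 0.95)
  expect_lte(sw["fprate"], 0.02)
  expect_lte(sp["fprate"], 0.02)
  expect_lte(rp["fprate"], 0.02)
})
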