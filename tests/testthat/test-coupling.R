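# Synchronization index, circular statistics, pairing, spectra,
# event-locked averages.

test_that("SI is exact on constructed phase series", {
  # constant 60 degree difference -> strength 1, angle 60
  th <- seq(-pi, pi, length.out = 500)
  si <- synchronization_index(th, th - pi / 3)
  expect_equal(si$strength, 1, tolerance = 1e-12)
  expect_equal(si$angle_deg, 60, tolerance = 1e-9)
  # uniform differences cancel
  d <- seq(0, 2 * pi, length.out = 361)[-361]
  si0 <- synchronization_index(d, numeric(360))
  expect_lt(si0$strength, 1e-10)
  # m = 4 hand computation: differences 0, 90, 0, 90
  si4 <- synchronization_index(c(0, pi / 2, 0, pi / 2), numeric(4))
  expect_equal(si4$strength, cos(pi / 4), tolerance = 1e-12)
  expect_equal(si4$angle_deg, 45, tolerance = 1e-9)
  expect_equal(si4$m, 4)
  expect_error(synchronization_index(numeric(0), numeric(0)), "m = 0")
})

test_that("SI angle is equivariant under rotations", {
  set.seed(9)
  a <- runif(200, -pi, pi)
  b <- runif(200, -pi, pi)
  s0 <- synchronization_index(a, b)
  # rotating both leaves SI unchanged
  s1 <- synchronization_index(a + 0.7, b + 0.7)
  expect_equal(s1$si, s0$si, tolerance = 1e-9)
  # rotating the reference by delta rotates the angle by delta
  s2 <- synchronization_index(a + 0.5, b)
  expect_equal(Arg(exp(1i * (s2$angle - s0$angle - 0.5))), 0,
               tolerance = 1e-9)
})

test_that("circular summary: concentration, null calibration, recovery", {
  cs <- circular_summary(rep(pi / 2, 50))
  expect_equal(cs$mean_deg, 90, tolerance = 1e-9)
  expect_equal(cs$R, 1, tolerance = 1e-12)
  expect_lt(cs$p, 1e-10)
  # uniform null: p > 0.05 in >= 94 percent of runs
  set.seed(10)
  rej <- replicate(200, circular_summary(runif(1000, -pi, pi))$p <= 0.05)
  expect_gte(mean(!rej), 0.94)
  # von Mises parameter recovery
  set.seed(19)
  ph <- rvonmises(351, -80 * pi / 180, 1)
  cs2 <- circular_summary(ph)
  expect_lt(abs(Arg(exp(1i * (cs2$mean_rad + 80 * pi / 180)))) * 180 / pi,
            10)
  expect_lt(cs2$p, 0.05)
})

test_that("Watson-Williams separates distinct mean directions", {
  set.seed(12)
  a <- rvonmises(100, 0, 4)
  b <- rvonmises(100, pi / 3, 4)
  ww <- watson_williams(a, b)
  expect_lt(ww$p, 0.01)
  c2 <- rvonmises(100, 0, 4)
  ww0 <- watson_williams(a, c2)
  expect_gt(ww0$p, 0.001)
})

test_that("nearest-event pairing recovers constructed shifts and correlations", {
  ev <- function(t, amp = 1)
    events_table(kind = "spindle", onset = t, peak = t + 0.1,
                 offset = t + 0.5, amplitude = amp)
  a <- ev(seq(10, 200, by = 3), amp = rnorm(64) + 5)
  # identical lists: zero delays, perfect amplitude correlation
  pr0 <- pair_nearest_events(a, a, max_gap = 1)
  expect_true(all(pr0$pairs$delay_s == 0))
  expect_equal(pr0$amplitude_cor, 1, tolerance = 1e-12)
  # shifted by -83 ms
  b <- a; b$onset_s <- b$onset_s - 0.083
  prs <- pair_nearest_events(a, b, max_gap = 1)
  expect_equal(prs$median_delay_s, -0.083, tolerance = 1e-9)
  expect_lt(prs$p_wilcoxon, 0.01)
  # correlated amplitudes recovered within 0.1
  set.seed(13)
  n <- 343
  z <- rnorm(n); x <- z + rnorm(n); y <- 0.5 * z + sqrt(1 - 0.25) *
    rnorm(n) + 0.5 * rnorm(n)
  rho_true <- cor(x, y)
  aa <- ev(seq(10, by = 2, length.out = n), amp = x)
  bb <- ev(seq(10, by = 2, length.out = n) + 0.05, amp = y)
  prc <- pair_nearest_events(aa, bb, max_gap = 1)
  expect_lt(abs(prc$amplitude_cor - rho_true), 0.02)
})

test_that("event rate histogram finds an injected pre-onset peak and is flat under the null", {
  set.seed(14)
  refs <- events_table(kind = "spindle", onset = sort(runif(300, 20, 580)),
                       peak = 0, offset = 0, amplitude = 1)
  # points injected 0.32 s before each reference
  pts <- events_table(kind = "swr", onset = refs$onset_s - 0.32,
                      peak = refs$onset_s - 0.32,
                      offset = refs$onset_s - 0.3, amplitude = 1)
  h <- event_rate_histogram(pts, refs, window = 1, bin = 0.1, seed = 2)
  expect_equal(h$peak_time_s, -0.35, tolerance = 0.051)
  # Poisson points independent of references stay inside the band
  pts0 <- events_table(kind = "swr", onset = sort(runif(400, 0, 600)),
                       peak = sort(runif(400, 0, 600)), offset = 0,
                       amplitude = 1)
  h0 <- event_rate_histogram(pts0, refs, window = 1, bin = 0.1, seed = 3)
  inside <- h0$rate >= h0$shuffle_lo & h0$rate <= h0$shuffle_hi
  expect_gte(mean(inside), 0.9)
})

test_that("spectral summary: identity, delay, independence", {
  fs <- 250
  set.seed(15)
  x <- as.numeric(bandpass_fir(rnorm(fs * 120), fs, c(2, 30)))
  s_id <- spectral_summary(x, x, fs)
  sel <- s_id$freq > 3 & s_id$freq < 25
  expect_true(all(s_id$coherence[sel] > 0.99))
  expect_equal(s_id$peak_lag_s, 0)
  expect_true(all(s_id$pxx >= 0))
  # y = x delayed by 88 ms -> peak lag 88 ms (positive: y lags x)
  d <- round(0.088 * fs)
  y <- c(rep(0, d), x[1:(length(x) - d)])
  s_del <- spectral_summary(x, y, fs)
  expect_equal(s_del$peak_lag_s, d / fs, tolerance = 1 / fs + 1e-9)
  # independent noises: coherence near the bias floor for k segments
  y2 <- rnorm(length(x))
  s_ind <- spectral_summary(x, y2, fs, seg_s = 4)
  k <- floor((length(x) / fs / 4) * 2 - 1)
  expect_lt(mean(s_ind$coherence), 1 / k + 0.05)
})

test_that("event-locked TFR localizes injected bursts and is scale invariant", {
  fs <- 250
  set.seed(16)
  dur <- 600
  n <- dur * fs
  x <- pink_noise(n, fs, 1, 1)
  tt <- (0:(n - 1)) / fs
  evt <- seq(20, dur - 20, by = 2.7)
  for (ctr in evt) {
    idx <- which(tt >= ctr - 0.25 & tt < ctr + 0.25)
    x[idx] <- x[idx] + 3 * sin(2 * pi * 12 * (tt[idx] - ctr)) *
      0.5 * (1 + cos(2 * pi * (tt[idx] - ctr) / 0.5))
  }
  tf <- event_locked_tfr(x, fs, evt, freqs = seq(6, 18, by = 2),
                         window = c(-1, 1))
  i12 <- which(tf$freqs == 12)
  it0 <- which.min(abs(tf$times))
  expect_gt(tf$tfr[i12, it0], 50)  # percent increase at 12 Hz, t = 0
  off <- which.min(abs(tf$times + 0.9))
  expect_gt(tf$tfr[i12, it0], 3 * max(tf$tfr[i12, off], 1))
  # doubling the gain leaves percent change unchanged
  tf2 <- event_locked_tfr(2 * x, fs, evt, freqs = seq(6, 18, by = 2),
                          window = c(-1, 1))
  expect_equal(tf2$tfr, tf$tfr, tolerance = 1e-9)
  # null: stationary noise with random events -> near zero percent change
  set.seed(17)
  x0 <- pink_noise(n, fs, 1, 1)
  ev0 <- sort(runif(220, 20, dur - 20))
  tf0 <- event_locked_tfr(x0, fs, ev0, freqs = c(8, 12, 16),
                          window = c(-1, 1))
  expect_lt(max(abs(rowMeans(tf0$tfr))), 5)
})

test_that("event-locked wavelet average peaks at the packet frequency and time", {
  fs <- 250
  set.seed(18)
  dur <- 400
  n <- dur * fs
  x <- pink_noise(n, fs, 1, 0.5)
  tt <- (0:(n - 1)) / fs
  evt <- seq(20, dur - 20, by = 3.1)
  for (ctr in evt) {
    idx <- which(tt >= ctr - 0.2 & tt < ctr + 0.2)
    x[idx] <- x[idx] + 4 * sin(2 * pi * 10 * (tt[idx] - ctr)) *
      exp(-(tt[idx] - ctr)^2 / (2 * 0.07^2))
  }
  wa <- event_locked_wavelet_average(x, fs, evt, epoch_s = 4,
                                     target_fs = 125, flim = c(1, 40),
                                     voices = 10)
  pk <- which(wa$mag == max(wa$mag), arr.ind = TRUE)
  expect_lt(abs(wa$freqs[pk[1]] - 10) / 10, 0.2)
  expect_lt(abs(wa$times[pk[2]]), 0.1)
  # averaging identity: k identical epochs equal one epoch
  wa1 <- event_locked_wavelet_average(x, fs, evt[5], epoch_s = 4,
                                      target_fs = 125, flim = c(1, 40),
                                      voices = 10)
  wak <- event_locked_wavelet_average(x, fs, rep(evt[5], 4), epoch_s = 4,
                                      target_fs = 125, flim = c(1, 40),
                                      voices = 10)
  expect_equal(wak$mag, wa1$mag, tolerance = 1e-12)
})
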