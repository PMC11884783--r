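# Synthetic-data generators: reproducibility, ground-truth consistency,
# round trips through the analysis pipeline.

test_that("generators are deterministic functions of the seed", {
  a <- gen_nrem_lfp(duration = 60, seed = 5)
  b <- gen_nrem_lfp(duration = 60, seed = 5)
  expect_identical(a$lfp, b$lfp)
  expect_identical(a$truth, b$truth)
  c2 <- gen_nrem_lfp(duration = 60, seed = 6)
  expect_false(identical(a$lfp, c2$lfp))
})

test_that("zero event rates give event-free signals and empty detections", {
  g <- gen_nrem_lfp(duration = 120, fs = 500, seed = 7, sw_rate = 0,
                    sp_rate = 0, swr_rate = 0, swr_freq = 120)
  expect_equal(nrow(g$truth), 0)
  hyp <- hypnogram_all_nrem(120)
  expect_equal(nrow(detect_spindles(g$lfp, g$fs, hyp)), 0)
  # on a pure 1/f background the SD-relative slow-wave rules admit only
  # chance-level events
  expect_lte(nrow(detect_slow_waves(g$lfp, g$fs, hyp)) / 120, 0.15)
})

test_that("pink noise has the requested spectral slope and SD", {
  set.seed(8)
  x <- pink_noise(2^16, 1000, alpha = 1, sd = 2)
  expect_equal(sd(x), 2, tolerance = 0.01)
  P <- abs(fft(x))^2
  f <- (0:(2^16 - 1)) * 1000 / 2^16
  sel <- f > 1 & f < 100
  slope <- coef(lm(log(P[sel]) ~ log(f[sel])))[2]
  expect_lt(abs(slope + 1), 0.15)
})

test_that("von Mises sampler matches its target distribution", {
  set.seed(9)
  ph <- rvonmises(4000, mu = 2, kappa = 3)
  cs <- circular_summary(ph)
  expect_lt(abs(Arg(exp(1i * (cs$mean_rad - 2)))), 0.06)
  # R for kappa = 3 is I1(3)/I0(3)
  expect_lt(abs(cs$R - besselI(3, 1) / besselI(3, 0)), 0.03)
  # kappa = 0 is uniform: Rayleigh nonsignificant in >= 94 percent
  set.seed(14)
  ns <- replicate(100, circular_summary(rvonmises(300, 0, 0))$p > 0.05)
  expect_gte(mean(ns), 0.94)
})

test_that("spindle phase coupling in the generator round-trips through the SI", {
  g <- gen_nrem_lfp(duration = 1500, fs = 250, seed = 10,
                    sw_rate = 0.5, sw_amp_sd = 5,
                    sp_rate = 0.35, sp_amp_sd = 6, phi0_deg = 150,
                    kappa = 6, swr_rate = 0, swr_freq = 60)
  truth_sw <- g$truth[g$truth$kind == "slow_wave", ]
  si <- sw_spindle_coupling(g$lfp, g$lfp, g$fs, truth_sw, ref = "peak_s")
  cs <- circular_summary(si$angle_deg * pi / 180)
  expect_gte(nrow(si), 200)
  expect_lt(abs(Arg(exp(1i * (cs$mean_rad - 150 * pi / 180)))) * 180 / pi,
            10)
  # strength above the uniform null 95th percentile
  null_q <- quantile(replicate(300, {
    m <- stats::median(si$m)
    Mod(mean(exp(1i * runif(m, -pi, pi))))
  }, ), 0.95)
  expect_gt(stats::median(si$strength), null_q)
})

test_that("phase-locked spike generator recovers mu and respects rate scaling", {
  fs <- 500
  t <- seq(0, 600, by = 1 / fs)
  ph <- Arg(exp(1i * 2 * pi * 1 * t))
  sp <- gen_phase_locked_spikes(ph, fs, mu = -118 * pi / 180, kappa = 2,
                                rate = 4, seed = 11)
  cs <- circular_summary(ph[pmin(round(sp * fs) + 1, length(ph))])
  expect_lt(abs(Arg(exp(1i * (cs$mean_rad + 118 * pi / 180)))) * 180 / pi,
            10)
  sp2 <- gen_phase_locked_spikes(ph, fs, mu = -118 * pi / 180, kappa = 2,
                                 rate = 8, seed = 12)
  cs2 <- circular_summary(ph[pmin(round(sp2 * fs) + 1, length(ph))])
  expect_lt(abs(Arg(exp(1i * (cs2$mean_rad - cs$mean_rad)))) * 180 / pi,
            10)
  expect_gt(length(sp2), 1.5 * length(sp))
})

test_that("session generator produces state-appropriate signals", {
  g <- gen_session(states = c("NREM", "NREM"), seg_s = 120, fs = 250,
                   seed = 12)
  expect_equal(unique(g$truth_bins$label), "NREM")
  # permuting states permutes the truth labels
  g2 <- gen_session(states = c("REM", "Wake"), seg_s = 120, fs = 250,
                    seed = 12)
  expect_equal(g2$truth$label, c("REM", "Wake"))
  expect_equal(length(g$mpfc), 2 * 120 * 250)
})

test_that("noiseless evoked fixture recovers template parameters to fit precision", {
  g <- gen_evoked_sweeps(n_sweeps = 1, noise_sd_mV = 0, amp_mV = 6,
                         latency_ms = 8, rise_ms = 1.2, seed = 13)
  m <- characterize_epsp(g$sweeps[, 1], g$fs, g$stim_time)
  expect_lt(abs(m$amplitude_mV - 6) / 6, 0.01)
  expect_lt(abs(m$latency_ms - 8), 0.4)
})
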