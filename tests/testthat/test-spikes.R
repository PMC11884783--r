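# Spike detection, artifact rejection, sorting, PETH, phase locking.


test_that("spike detection hits injected spikes with few false positives", {
  tet <- make_tetrode(dur = 30, seed = 21,
                      units = list(list(rate = 5, amp = c(8, 3, 1, 1))))
  tr <- detect_spikes(tet$x, tet$fs)
  truth <- tet$truth[[1]]
  hit <- vapply(truth, function(s) any(abs(tr$times - s) < 0.001),
                logical(1))
  fp <- vapply(tr$times, function(s) all(abs(truth - s) > 0.0015),
               logical(1))
  expect_gte(mean(hit), 0.99)
  # a -4 robust-SD threshold on a Gaussian background admits chance
  # crossings at a rate set by Rice's formula (~0.3-0.5/s here); the
  # downstream feature clustering is what removes them
  expect_lte(sum(fp) / 30, 0.6)
  # all-positive signal has no negative crossings
  pos <- abs(tet$x)
  expect_equal(length(detect_spikes(pos, tet$fs)$times), 0)
  expect_error(detect_spikes(tet$x, 5000), "too low")
})

test_that("shadow period collapses twin crossings into one spike", {
  fs <- 20000
  set.seed(22)
  x <- rnorm(fs, 0, 1)
  # two crossings 0.5 ms apart -> one detection
  i <- 10000
  x[i:(i + 3)] <- -12
  x[(i + 10):(i + 13)] <- -12   # 0.5 ms later
  tr <- detect_spikes(matrix(x, ncol = 1), fs)
  expect_equal(sum(tr$times > 0.49 & tr$times < 0.51), 1)
})

test_that("artifact rejection masks +/- 250 ms and merges close artifacts", {
  fs <- 20000
  set.seed(23)
  x <- rnorm(10 * fs, 0, 1)
  x[2 * fs] <- 25          # one artifact
  x[5 * fs] <- 30          # two artifacts 300 ms apart -> merged
  x[5 * fs + round(0.3 * fs)] <- -28
  ra <- reject_artifacts(x, fs)
  expect_equal(nrow(ra$intervals), 2)
  expect_lt(abs((ra$intervals$end_s[1] - ra$intervals$start_s[1]) - 0.5),
            0.01)
  expect_lt(abs((ra$intervals$end_s[2] - ra$intervals$start_s[2]) - 0.8),
            0.01)
  expect_false(any(ra$mask[(2 * fs - 100):(2 * fs + 100)]))
  # clean noise: empty mask
  ra0 <- reject_artifacts(rnorm(fs, 0, 1), fs, thr_sd = 16)
  expect_equal(nrow(ra0$intervals), 0)
  # spikes and masked intervals are disjoint
  tr <- detect_spikes(matrix(x, ncol = 1), fs, mask = ra$mask)
  bad <- ra$intervals
  inside <- vapply(tr$times, function(s)
    any(s >= bad$start_s & s <= bad$end_s), logical(1))
  expect_false(any(inside))
})

test_that("two-template tetrode fixture sorts at >= 95 percent accuracy", {
  tet <- make_tetrode(dur = 120, seed = 24)
  det <- detect_spikes(tet$x, tet$fs)
  # restrict to truth-aligned detections (sorting accuracy measures the
  # sorter, not chance threshold crossings)
  lab <- rep(NA_integer_, length(det$times))
  for (u in 1:2) {
    for (s in tet$truth[[u]]) {
      i <- which.min(abs(det$times - s))
      if (abs(det$times[i] - s) < 0.001) lab[i] <- u
    }
  }
  keep <- which(!is.na(lab))
  det$times <- det$times[keep]
  det$snippets <- det$snippets[keep, , , drop = FALSE]
  det$unit <- det$unit[keep]
  lab <- lab[keep]
  tr <- sort_units(det)
  ok <- !is.na(tr$unit)
  expect_gt(sum(ok), 400)
  # majority mapping of clusters onto true units
  tab <- table(tr$unit[ok], lab[ok])
  map <- apply(tab, 1, which.max)
  acc <- mean(map[as.character(tr$unit[ok])] == lab[ok])
  expect_gte(acc, 0.95)
})

test_that("single template yields a single cluster; infinite radius keeps all", {
  tet <- make_tetrode(dur = 60, seed = 25,
                      units = list(list(rate = 6, amp = c(10, 3, 1, 1))))
  det <- detect_spikes(tet$x, tet$fs)
  truth <- tet$truth[[1]]
  keep <- which(vapply(det$times, function(s)
    any(abs(truth - s) < 0.001), logical(1)))
  det$times <- det$times[keep]
  det$snippets <- det$snippets[keep, , , drop = FALSE]
  det$unit <- det$unit[keep]
  tr <- sort_units(det, mahal_max = Inf)
  expect_equal(length(unique(stats::na.omit(tr$unit))), 1)
  expect_false(anyNA(tr$unit))
})

test_that("PETH z-scoring classifies activated, suppressed and null units", {
  set.seed(26)
  dur <- 600
  ev <- sort(runif(150, 10, dur - 10))
  # null: homogeneous Poisson
  sp0 <- sort(runif(dur * 5, 0, dur))
  p0 <- peth_zscore(sp0, ev, seed = 1)
  expect_equal(p0$classification, "unmodulated")
  # activated: extra spikes at event + 50 ms
  sp1 <- sort(c(sp0, rep(ev + 0.05, each = 2) +
                  rnorm(2 * length(ev), 0, 0.005)))
  p1 <- peth_zscore(sp1, ev, seed = 1)
  expect_equal(p1$classification, "activated")
  expect_gt(max(p1$z[p1$mids > 0.03 & p1$mids < 0.08]), 2)
  # suppressed: delete spikes in event + 0..150 ms
  del <- vapply(sp0, function(s) any(s - ev > 0 & s - ev < 0.15),
                logical(1))
  p2 <- peth_zscore(sp0[!del], ev, seed = 1)
  expect_equal(p2$classification, "suppressed")
})

test_that("PETH z-values are approximately standard normal under the null", {
  set.seed(27)
  dur <- 400
  zpool <- c()
  for (k in 1:10) {
    ev <- sort(runif(60, 10, dur - 10))
    sp <- sort(runif(dur * 4, 0, dur))
    p <- peth_zscore(sp, ev, n_shuffles = 60, seed = k)
    zpool <- c(zpool, p$z[is.finite(p$z)])
  }
  ks <- suppressWarnings(stats::ks.test(zpool, "pnorm"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("spike-field phase locking recovers the locking phase and flags empty gates", {
  fs <- 1000
  t <- seq(0, 300, by = 1 / fs)
  lfp <- sin(2 * pi * 12 * t)
  ph <- instantaneous_phase(lfp, fs, c(7, 15))
  sp <- gen_phase_locked_spikes(ph, fs, mu = -80 * pi / 180, kappa = 3,
                                rate = 3, seed = 28)
  res <- spike_phase_locking(sp, ph, fs)
  expect_false(res$flagged)
  expect_lt(abs(Arg(exp(1i * (res$mean_rad + 80 * pi / 180)))) * 180 / pi,
            10)
  expect_lt(res$p, 1e-6)
  # Poisson spikes: nonsignificant in >= 94 percent of seeded runs
  nsig <- replicate(50, {
    sp0 <- gen_phase_locked_spikes(ph, fs, kappa = 0, rate = 2,
                                   seed = sample.int(1e6, 1))
    spike_phase_locking(sp0, ph, fs)$p > 0.05
  })
  expect_gte(mean(nsig), 0.94)
  # gate excluding all spikes
  res2 <- spike_phase_locking(sp, ph, fs, gate_times = -10, gate_s = 0.1)
  expect_true(res2$flagged)
})
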