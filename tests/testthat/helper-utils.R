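# shared test helpers

unwrap_phase <- function(p) {
  dp <- Arg(exp(1i * diff(p)))
  cumsum(c(p[1], dp))
}

# cached model simulation shared across acceptance tests (built on
# first use; ~1000 s run takes a few seconds with the compiled core)
.somnet_test_cache <- new.env(parent = emptyenv())

model_session <- function(duration = 1020, seed = 1) {
  key <- sprintf("sim_%d_%d", duration, seed)
  if (is.null(.somnet_test_cache[[key]])) {
    p <- model_params()
    .somnet_test_cache[[key]] <-
      simulate_network(p, duration = duration, burn_in = 20, seed = seed,
                       noise_sd = p$noise.sd)
  }
  .somnet_test_cache[[key]]
}

model_session_stats <- function(duration = 1020, seed = 1) {
  key <- sprintf("an_%d_%d", duration, seed)
  if (is.null(.somnet_test_cache[[key]])) {
    .somnet_test_cache[[key]] <-
      analyze_nrem_session(model_session(duration, seed), seed = seed)
  }
  .somnet_test_cache[[key]]
}

make_tetrode <- function(dur = 60, fs = 20000, seed = 1,
                         units = list(list(rate = 4, amp = c(8, 2, 1, 1)),
                                      list(rate = 4, amp = c(1, 1, 7, 3))),
                         noise_sd = 1) {
  set.seed(seed)
  n <- dur * fs
  x <- matrix(rnorm(n * 4, 0, noise_sd), n, 4)
  # biphasic 1 ms template: sharp trough then small rebound
  tmpl <- c(-0.2, -0.6, -1, -0.7, -0.2, 0.15, 0.25, 0.18, 0.1, 0.05,
            0.02, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  truth <- list()
  for (u in seq_along(units)) {
    nt <- rpois(1, units[[u]]$rate * (dur - 1))
    st <- sort(runif(nt, 0.5, dur - 0.5))
    st <- st[c(TRUE, diff(st) > 0.003)]
    idx <- round(st * fs)
    for (i in idx) for (ch in 1:4) {
      seg <- i:(i + length(tmpl) - 1)
      x[seg, ch] <- x[seg, ch] + tmpl * units[[u]]$amp[ch]
    }
    truth[[u]] <- idx / fs
  }
  list(x = x, fs = fs, truth = truth)
}
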