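#!/usr/bin/env Rscript
# Runs the NREM event detectors on the simulated session written by
# 01_simulate.R: slow waves on the cortical and reuniens membrane
# potentials, spindles on both, SWRs on CA1. Event tables go to
# results/events/ as TSV.
#
# Run from the repository root:  Rscript analysis/02_detect_events.R

suppressMessages(library(somnet))
rec <- read_recording("results/session")
fs <- rec$fs[["cx"]]
t0 <- rec$meta$t0
hyp <- hypnogram_all_nrem(t0 + length(rec$signals$cx) / fs)

ev <- list(
  sw_cx = detect_slow_waves(rec$signals$cx, fs, hyp, t0 = t0,
                            channel = "cx"),
  sw_reu = detect_slow_waves(rec$signals$reu, fs, hyp, t0 = t0,
                             channel = "reu"),
  sp_cx = detect_spindles(rec$signals$cx, fs, hyp, t0 = t0,
                          channel = "cx"),
  sp_reu = detect_spindles(rec$signals$reu, fs, hyp, t0 = t0,
                           channel = "reu"),
  swr = detect_swrs(rec$signals$ca1, fs, hyp, t0 = t0, channel = "ca1"))

dir.create("results/events", recursive = TRUE, showWarnings = FALSE)
for (nm in names(ev)) {
  write_events_tsv(ev[[nm]], file.path("results/events",
                                       paste0(nm, ".tsv")))
  message(sprintf("%-7s %4d events (%.2f/s)", nm, nrow(ev[[nm]]),
                  nrow(ev[[nm]]) / (length(rec$signals$cx) / fs)))
}
message("wrote results/events/*.tsv")
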