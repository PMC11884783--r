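#!/usr/bin/env Rscript
# Multi-regional coupling statistics of the simulated NREM session:
# slow-wave trough lags (reuniens re cortex), spindle-onset lags,
# slow-wave/spindle synchronization index (strength and preferred
# angle, cortical and reuniens amplitude), slow-wave phase at SWR
# times, and the SWR-rate histogram around cortical spindle onsets.
# Writes results/coupling_stats.tsv and results/swr_rate_hist.tsv.
#
# Run from the repository root:  Rscript analysis/03_coupling.R [seed]

suppressMessages(library(somnet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1

rec <- read_recording("results/session")
an <- analyze_nrem_session(rec, seed = seed)
print(an)

s <- an$stats
flat <- data.frame(statistic = names(unlist(s)),
                   value = as.numeric(unlist(s)))
dir.create("results", showWarnings = FALSE)
utils::write.table(flat, "results/coupling_stats.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
if (!is.null(an$swr_rate_hist)) {
  h <- an$swr_rate_hist
  utils::write.table(
    data.frame(time_s = h$mids, rate = h$rate,
               shuffle_lo = h$shuffle_lo, shuffle_hi = h$shuffle_hi),
    "results/swr_rate_hist.tsv", sep = "\t", row.names = FALSE,
    quote = FALSE)
}
message("wrote results/coupling_stats.tsv")
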