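#!/usr/bin/env Rscript
# Connectivity sweep over the strength of the bidirectional
# CA1-reuniens projections (scaling factors alpha on the two E-E
# pathways): per grid cell the SWR-locked reuniens-CA1 covariance peak,
# the pre-spindle SWR-rate peak-to-trough, the slow-wave-band CA1
# deflection around cortical slow-wave troughs, and the mean slow-wave
# phase at SWRs (Rayleigh-gated). A 3 x 3 grid at 220 s per cell keeps
# the run to a few minutes; the grid and duration are arguments.
#
# Run from the repository root:
#   Rscript analysis/04_sweep.R [duration_s] [seed]

suppressMessages(library(somnet))
args <- commandArgs(trailingOnly = TRUE)
dur <- if (length(args) >= 1) as.numeric(args[1]) else 220
seed <- if (length(args) >= 2) as.integer(args[2]) else 1

res <- run_connectivity_sweep(model_params(),
                              alpha_ca1_reu = c(0.5, 1, 2),
                              alpha_reu_ca1 = c(0.5, 1, 2),
                              duration = dur, seed = seed)
print(res, digits = 3)
dir.create("results", showWarnings = FALSE)
utils::write.table(res, "results/connectivity_sweep.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message("wrote results/connectivity_sweep.tsv")

# the decoupled corner (alpha = 0) as a reference: covariance at chance
res0 <- run_connectivity_sweep(model_params(), alpha_ca1_reu = 0,
                               alpha_reu_ca1 = 0, duration = dur,
                               seed = seed)
print(res0, digits = 3)
utils::write.table(res0, "results/connectivity_sweep_decoupled.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
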