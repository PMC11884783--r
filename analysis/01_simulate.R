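#!/usr/bin/env Rscript
# Simulates the calibrated hippocampo-thalamo-cortical network for a
# full NREM session (1000 s analysed after a 20 s burn-in, dt = 1 ms,
# seeded background input on the cortical and CA3 populations) and
# writes the membrane-potential channels to a recording container under
# results/session/.
#
# Run from the repository root:  Rscript analysis/01_simulate.R [seed]

suppressMessages(library(somnet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1

params <- model_params()
message(sprintf("integrating 17 rate equations: 1020 s at dt = 1 ms (seed %d)",
                seed))
tr <- simulate_nrem_session(params, duration = 1020, burn_in = 20,
                            seed = seed)
rec <- as_recording(tr)
dir.create("results", showWarnings = FALSE)
write_recording(rec, "results/session")
message("channels: ", paste(names(rec$signals), collapse = ", "))
message("wrote results/session (fs = 1000 Hz, ",
        length(rec$signals$cx) / 1000, " s per channel)")
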