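#!/usr/bin/env Rscript
# Evoked transitions: pulse-triggered state switches in the excitable
# regimes, and the paradoxical excitatory-evoked DOWN state of the
# adapting inhibition-stabilized network.

library(nremdyn)
dir.create("results/evoked", showWarnings = FALSE, recursive = TRUE)

## Excitable_DOWN (hippocampus-like): activating pulses evoke SWR-like UPs.
## A deep operating point keeps the spontaneous rate low, so the pulse
## effect is visible above the baseline.
p <- rate_pop_params(w = 6, b = 1, I = 2.1)
tmpl <- pulse_spec(amplitude = 0, onset = 400, width = 5, target = "r")
amps <- c(0, 0.3, 0.6, 0.9, 1.2, 1.8, 2.5)
pr <- evoked_probability(p, ou_params(), tmpl, amplitudes = amps,
                         n_trials = 100, seed = 501)
cat("Probability of evoking a transient UP state vs pulse amplitude\n")
cat("(Excitable_DOWN, with noise):\n")
print(pr, row.names = FALSE, digits = 3)
write.table(pr, "results/evoked/excitable_down_probability.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

## aISN Excitable_UP: an excitatory kick to E evokes a transient DOWN
pe <- ei_params()
cat(sprintf("\naISN regime at defaults: %s\n", ei_regime(pe)$label))
kick <- pulse_spec(amplitude = 0, onset = 1000, width = 10, target = "r_e")
amps_e <- c(0, 0.2, 0.4, 0.6, 1, 2)
pr_e <- evoked_probability(pe, ou_params(sigma = 0), kick,
                           amplitudes = amps_e, n_trials = 1, seed = 502)
cat("Deterministic threshold curve for excitatory-evoked DOWN states:\n")
print(pr_e, row.names = FALSE, digits = 3)
write.table(pr_e, "results/evoked/aisn_excitatory_threshold.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

## separatrix geometry: the frozen-adaptation system is bistable at low
## drive (the UP basin is bounded; kicks across the boundary evoke DOWNs)
pe_low <- ei_params(I_e = 0)
sep <- ei_separatrix(pe_low, a_frozen = 0)
write.table(as.data.frame(unclass(sep)),
            "results/evoked/aisn_separatrix.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("\nSeparatrix polyline: %d points; saddle at (%.3f, %.3f)\n",
            nrow(sep), attr(sep, "saddle")[1], attr(sep, "saddle")[2]))
cat("Outputs in results/evoked/\n")
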