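#!/usr/bin/env Rscript
# End-to-end event detection on ground-truthed synthetic recordings:
# NREM scoring, PETH-calibrated slow-wave detection, SWR detection, and
# delta-power stratification of UP/DOWN durations.

library(nremdyn)
dir.create("results/events", showWarnings = FALSE, recursive = TRUE)

## slow waves ---------------------------------------------------------------
rec <- synth_updown_recording(synth_config(length_s = 300, seed = 401))
thr <- calibrate_sw_thresholds(rec$lfp, rec$spikes, sensitivity = 0.5)
cat(sprintf("Calibrated thresholds: delta peak %.2f / window %.2f SD; gamma %.2f / %.2f\n",
            thr$delta[["peak"]], thr$delta[["window"]],
            thr$gamma[["peak"]], thr$gamma[["window"]]))
sw <- detect_slow_waves(rec$lfp, rec$spikes, thresholds = thr)
dn <- sw[sw$label == "DOWN", ]
truth_dn <- rec$truth[rec$truth$label == "DOWN", ]
mid <- (dn$start + dn$stop) / 2
prec <- mean(vapply(mid, function(m)
  any(truth_dn$start <= m & truth_dn$stop >= m), logical(1)))
midt <- (truth_dn$start + truth_dn$stop) / 2
rec_ <- mean(vapply(midt, function(m)
  any(dn$start <= m & dn$stop >= m), logical(1)))
cat(sprintf("Slow waves: %d truth, %d detected, precision %.3f recall %.3f\n",
            nrow(truth_dn), nrow(dn), prec, rec_))
write_intervals(sw, "results/events/slow_waves.tsv")

## delta stratification ------------------------------------------------------
dc <- delta_conditioned_stats(sw, rec$lfp, channel = 1, n_groups = 3)
cat("\nUP/DOWN durations by surrounding delta power (3 groups):\n")
print(dc$groups[, c("group", "mean_up", "mean_down", "cv_up", "cv_down")],
      row.names = FALSE, digits = 3)
write.table(dc$groups, "results/events/delta_groups.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## SWRs ----------------------------------------------------------------------
swr_rec <- synth_swr_recording(synth_config(length_s = 300, seed = 402))
ev <- detect_swr(swr_rec$lfp, deep = 1, superficial = 2)
midd <- (ev$start + ev$stop) / 2
tr <- swr_rec$truth
p2 <- mean(vapply(midd, function(m)
  any(tr$start - 0.02 <= m & tr$stop + 0.02 >= m), logical(1)))
midt2 <- (tr$start + tr$stop) / 2
r2 <- mean(vapply(midt2, function(m)
  any(ev$start - 0.02 <= m & ev$stop + 0.02 >= m), logical(1)))
cat(sprintf("\nSWRs: %d truth, %d detected, precision %.3f recall %.3f\n",
            nrow(tr), nrow(ev), p2, r2))
cat(sprintf("Detected SWR durations: mean %.0f ms (truth %.0f ms)\n",
            1000 * mean(ev$stop - ev$start),
            1000 * mean(tr$stop - tr$start)))
write_intervals(ev, "results/events/swr.tsv")
cat("Outputs in results/events/\n")
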