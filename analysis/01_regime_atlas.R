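#!/usr/bin/env Rscript
# Regime atlas of the adapting recurrent population over the I-w plane.
#
# Classifies the deterministic regime on a grid at b = 1 and simulates
# dwell-time statistics per cell under the default OU noise. Expected
# structure: a monostable band at weak recurrence; for w above the
# critical value, Excitable_DOWN at low drive and Excitable_UP at high
# drive, separated by an oscillatory or bistable center depending on w.

library(nremdyn)

res <- run_regime_atlas(list(
  base = list(w = 6, b = 1, I = 2.5),
  axis1 = list(name = "I", values = seq(2.1, 2.9, by = 0.1)),
  axis2 = list(name = "w", values = c(3, 5, 6, 6.3, 6.6)),
  duration = 30000,
  noise = list(theta = 0.05, sigma = 0.25),
  seed = 101,
  out_dir = "results/atlas"))

rmap <- read.table(res$regime_map, header = TRUE, sep = "\t")
cat("\nRegime counts over the grid:\n")
print(table(rmap$regime))
cat("\nRegimes along w = 6 (drive sweep):\n")
print(rmap[rmap$w == 6, c("I", "regime")], row.names = FALSE)

dmap <- read.table(res$duration_map, header = TRUE, sep = "\t")
ok <- dmap[dmap$status == "ok" & dmap$w == 6, ]
cat("\nDwell-time statistics along w = 6 (alternating cells):\n")
print(ok[, c("I", "mean_up", "mean_down", "cv_up", "cv_down", "ratio")],
      row.names = FALSE, digits = 3)
cat("\nNote the asymmetry flip: DOWN-dominated, variable-DOWN cells at low",
    "drive versus UP-dominated, variable-UP cells at high drive.\n")
cat("Outputs in results/atlas/\n")
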