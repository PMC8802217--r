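#!/usr/bin/env Rscript
# Step 2 — per-trial kinetics.
#
# Reloads the raw simulated trials from disk, runs the full measurement
# pipeline (stride segmentation, quintic-spline marker smoothing, kinematic
# seeding and kinetic optimization of v0, impulse integration, COM power,
# girdle split), and compares each recovered metric with the generator's
# ground truth.

library(burstloco)

out <- "results/simulated"
truth <- read.csv(file.path(out, "ground_truth.csv"))

perf <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
  b <- load_trial(file.path(out, "trials", sprintf("%s_force.csv", truth$trial_id[i])),
                  file.path(out, "trials", sprintf("%s_marker.csv", truth$trial_id[i])),
                  meta = list(body_mass = truth$body_mass_kg[i],
                              rabbit_id = truth$rabbit_id[i],
                              trial_id = truth$trial_id[i]))
  process_trial(b)
}))
write.csv(perf, "results/performance.csv", row.names = FALSE)

rel <- function(x, y) 100 * abs(x - y) / abs(y)
cat("recovery vs ground truth (median | 90th pct):\n")
cat(sprintf("  a_COM : %.2f%% | %.2f%%\n",
            median(rel(perf$a_com, truth$a_mean)),
            quantile(rel(perf$a_com, truth$a_mean), 0.9)))
cat(sprintf("  v0    : %.3f | %.3f m/s\n",
            median(abs(perf$v0 - truth$v0)),
            quantile(abs(perf$v0 - truth$v0), 0.9)))
cat(sprintf("  v_esc : %.2f%% | %.2f%%\n",
            median(rel(perf$v_esc, truth$v_esc)),
            quantile(rel(perf$v_esc, truth$v_esc), 0.9)))
cat(sprintf("  P_COM : %.2f%% | %.2f%%\n",
            median(rel(perf$p_com, truth$p_com)),
            quantile(rel(perf$p_com, truth$p_com), 0.9)))
cat("wrote results/performance.csv\n")
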