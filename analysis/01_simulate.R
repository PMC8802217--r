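#!/usr/bin/env Rscript
# Step 1 — simulate the study's raw material.
#
# Generates (i) a set of force-plate + marker trials with known ground truth,
# written in the standard per-trial CSV formats, and (ii) an ontogenetic
# cohort (per-trial performance metrics, muscle architecture tables, collar
# status and survival durations) at the study conditions: 38 individuals
# (26 juveniles / 12 adults, 0.106-1.434 kg), ~5 usable trials each, peak
# acceleration quadratic in mass with vertex 0.74 kg, muscle power scaling
# as 2.2 M^1.32.

library(burstloco)

seed <- 20230901L
out <- "results/simulated"
dir.create(file.path(out, "trials"), recursive = TRUE, showWarnings = FALSE)

## raw trials: 25 rabbits' worth of single strides with realistic noise -----
set.seed(seed)
truth <- do.call(rbind, lapply(1:25, function(i) {
  p <- trial_sim_params(body_mass = runif(1, 0.4, 1.4),
                        v0_true = runif(1, 0, 0.4),
                        a_mean = runif(1, 2, 8),
                        force_noise_sd = 0.5, marker_noise_sd = 1e-3,
                        marker_dropout = 0.05, seed = seed + i)
  s <- simulate_trial(p, trial_id = sprintf("T%03d", i),
                      rabbit_id = sprintf("R%02d", i))
  write_trial(s$bundle,
              file.path(out, "trials", sprintf("T%03d_force.csv", i)),
              file.path(out, "trials", sprintf("T%03d_marker.csv", i)))
  data.frame(trial_id = sprintf("T%03d", i), rabbit_id = sprintf("R%02d", i),
             body_mass_kg = p$body_mass, a_mean = s$truth$a_mean,
             v0 = s$truth$v0, v_esc = s$truth$v_esc, p_com = s$truth$p_com,
             stroke_s = s$truth$stroke)
}))
write.csv(truth, file.path(out, "ground_truth.csv"), row.names = FALSE)
cat(sprintf("wrote %d raw trials with ground truth to %s\n", nrow(truth), out))

## the ontogenetic cohort ----------------------------------------------------
co <- simulate_cohort(cohort_sim_params(seed = seed))
write.csv(co$cohort, file.path(out, "cohort.csv"), row.names = FALSE)
write.csv(co$trials, file.path(out, "trial_metrics.csv"), row.names = FALSE)
write.csv(co$muscles, file.path(out, "muscles.csv"), row.names = FALSE)
cat(sprintf("cohort: %d individuals (%d juvenile / %d adult), %d trials, %d muscle rows\n",
            nrow(co$cohort), sum(co$cohort$age_class == "juvenile"),
            sum(co$cohort$age_class == "adult"), nrow(co$trials),
            nrow(co$muscles)))
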