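#!/usr/bin/env Rscript
# Step 7 — ecological scenarios.
#
# Evaluates the fitted peak-acceleration quadratic at a representative
# juvenile (0.8 kg) and adult (1.2 kg) and projects three
# constant-acceleration escape scenarios: distance in the first second, time
# to a 10 m refuge, and strides to the species' top recorded speed
# (11.1 m/s). The stride period for the stride-count scenario comes from the
# processed dataset (twice the mean hindlimb stroke duration).

library(burstloco)

trials <- read.csv("results/simulated/trial_metrics.csv")
d <- data.frame(mass = trials$body_mass_kg, response = trials$a_com,
                rabbit_id = trials$rabbit_id)
f <- fit_quadratic(d, "peak")

sc <- scenarios_from_fit(f, juv_mass = 0.8, adult_mass = 1.2, refuge = 10,
                         top_speed = 11.1,
                         stride_duration = 2 * mean(trials$stroke_s))
print(sc)

write.csv(data.frame(
  age = c("juvenile", "adult"),
  mass_kg = c(0.8, 1.2),
  accel_ms2 = as.numeric(sc$accelerations),
  distance_1s_m = as.numeric(sc$distance_1s),
  time_to_refuge_s = as.numeric(sc$time_to_refuge),
  strides_to_top = as.numeric(sc$strides_to_top)),
  "results/scenarios.csv", row.names = FALSE)
cat(sprintf("ratios: distance %.0f%%, time %.0f%%, stride difference %d\n",
            100 * sc$ratios["distance_ratio"], 100 * sc$ratios["time_ratio"],
            as.integer(sc$ratios["stride_difference"])))
cat("wrote results/scenarios.csv\n")
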