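# burstloco

Burst (accelerative) locomotion is how small prey mammals stay alive: a
cottontail-sized animal flushed by a predator wins or loses in the first
few tenths of a second. **burstloco** is an R package plus analysis workflow
for quantifying that performance across growth, from raw force-plate and
marker data to population-level inference:

* **Per-trial kinetics** — stride segmentation from two force plates,
  quintic-spline smoothing of the hip-marker trajectory, kinematically
  seeded and kinetically optimized initial velocity, and the core metrics:
  mean COM acceleration `a_COM = mean(F_FA)/M_b`, escape speed
  `v_esc = ∫F_FA dt / M_b + v0`, average COM mechanical power `P_COM` from
  positive fluctuations of COM energy over the hindlimb stroke, and
  fore/hind girdle accelerations.
* **Muscle power capacity** — the architecture chain
  `PCSA = MM·cosθ/(L_F·ρ)`, `F_max = 30 N/cm² · PCSA`,
  `V_max = 6.3 L_F/s`, `P_peak = 0.1·F_max·V_max`, and
  `P_musc = 2·ΣP_peak` over the hindlimb extensors.
* **Ontogenetic statistics** — quadratic performance–mass models with
  heteroscedastic errors (mixed-effects over trials, GLS over
  per-individual peaks), AICc model comparison, vertex (peak-performance
  mass) estimation with case-bootstrap CIs and a mass→age growth model,
  log-log allometry with geometric (1.00) vs mechanical (1.33) similarity
  verdicts, repeatability (ICC), Welch/Cohen's-d contrasts, Box-Cox
  standardization, one-tailed correlation and Fisher-z power analysis.
* **Path analysis** — recursive ML path models
  (M_b, P_musc → P_COM → a_COM plus a direct mass path) with χ², RMSEA and
  CFI fit indices and stepwise pruning of non-significant paths.
* **Escape scenarios** — constant-acceleration projections (distance in the
  first second, time to a 10 m refuge, strides to top recorded speed).
* **A synthetic study generator** — trials with exactly known ground truth
  and cohorts with designed quadratics, ICCs, allometry and
  survival-performance coupling, so every stage is validated by parameter
  recovery without any external download.

## Worked example

```r
library(burstloco)

# one noisy simulated trial (0.8 kg animal, half-sine acceleration pulse,
# mean 5 m/s^2, starting at 0.2 m/s) and its recovery
s <- simulate_trial(trial_sim_params(body_mass = 0.8, v0_true = 0.2,
                                     a_mean = 5, force_noise_sd = 0.5,
                                     marker_noise_sd = 1e-3, seed = 3))
process_trial(s$bundle)
#>   trial_id rabbit_id mass_kg    a_com        v0   v_esc   p_com p_com_per_kg
#> 1     sim1        r1     0.8 4.967714 0.2067913 1.44872 6.73242     8.415525
#>   stroke_s  fore_a   hind_a
#> 1    0.124 5.02297 4.878207
s$truth[c("a_mean", "v0", "v_esc")]
#> $a_mean [1] 4.999737
#> $v0     [1] 0.2
#> $v_esc  [1] 1.449934
```

The recovered acceleration (4.968 m/s² vs 5.000 true), initial velocity
(0.207 vs 0.200 m/s) and escape speed (1.4487 vs 1.4499 m/s) are within ~1%
under 0.5 N force noise and 1 mm marker noise — the pipeline's typical
accuracy.

The full analysis is a numbered workflow over the package:

```sh
Rscript analysis/01_simulate.R        # raw trials + ontogenetic cohort
Rscript analysis/02_process_trials.R  # per-trial kinetics, recovery report
Rscript analysis/03_muscle_power.R    # P_musc and its allometry
Rscript analysis/04_ontogeny.R        # quadratic fits, vertices, ICC, contrasts
Rscript analysis/05_path_model.R      # determinants of acceleration
Rscript analysis/06_survival.R        # performance vs survival + power
Rscript analysis/07_scenarios.R       # constant-acceleration projections
```

Each step prints its findings and writes tables under `results/`. On the
default simulated cohort, step 04 reports peak acceleration at 0.78 kg
[0.76, 0.80] (98 days), step 03 an allometric exponent of 1.29 [1.21, 1.37]
with the mechanical similarity exponent (1.33) inside the CI and the
geometric one (1.00) outside, and step 07 a juvenile that out-travels the
adult by ~1.5x in the first second.

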