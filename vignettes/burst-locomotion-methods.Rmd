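---
title: "Methods: burst locomotor performance from force-plate trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst locomotor performance from force-plate trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstloco)
```

## The measurement problem

Small mammals escape predators with short bursts of acceleration. On an
instrumented runway, each usable trial yields two synchronized streams: a
two-plate ground-reaction-force record (fore-aft and vertical channels,
500 Hz) and a 3-D hip-marker trajectory from high-speed video (250 Hz),
sharing a common trigger. From these, the pipeline derives per-trial
performance metrics:

* **Mean COM acceleration** `a_COM`: the mean fore-aft force over the stride
  divided by body mass `M_b`.
* **Escape speed** `v_esc`: the fore-aft impulse over mass plus the initial
  velocity,
  `v_esc = (1 / M_b) * integral(F_FA, t0, t_end) + v0`,
  evaluated by trapezoidal quadrature at the force sampling rate.
* **Initial velocity** `v0`: seeded from the kinematic (marker-derived)
  fore-aft velocity just before contact, then refined by matching the
  kinetic velocity profile `v(t; v0) = v0 + cumulative integral(F_FA)/M_b`
  to the kinematic profile in a least-squares sense. Because the objective
  is exactly quadratic in `v0`, the minimizer is closed form (the mean
  residual between the two profiles); a bounded golden-section search is
  retained as a numerical cross-check and must agree to 1e-6 m/s.
* **Average COM power** `P_COM`: positive increments of the COM's mechanical
  energy `E = KE + PE` (velocities by integrating the force channels,
  vertical velocity assumed zero at stride onset because trials start from a
  static crouch), accumulated over the stride and divided by the hindlimb
  stroke duration `t`.
* **Girdle accelerations**: per-plate mean `F_FA / M_b` over each plate's
  stance, with the earlier-contacting plate read as forelimb and the later
  as hindlimb. A trial whose whole stride lands on one plate is treated as
  hindlimb contact, since propulsion in the half-bound is hindlimb
  dominated.

Around the trial level, the package fits the ontogenetic layer: quadratic
performance-mass curves with heteroscedastic errors, the peak-performance
(vertex) mass and its age, log-log allometry of architecturally estimated
hindlimb muscle power, repeatability, a recursive path model of what drives
acceleration, survival correlations and their statistical power, and
constant-acceleration escape scenarios.

## Work-energy bookkeeping and the power-acceleration relation

Two identities tie the kinetic quantities together. First, for a level,
monotonic acceleration from rest, the work-energy theorem reads
`1/2 M_b v_esc^2 = P_COM * t`, with `t` the hindlimb stroke duration over
which propulsive work is performed. Second, under constant average power the
COM velocity grows as `v = sqrt(2 P t / M)`, and differentiating gives the
instantaneous acceleration `a = sqrt(P / (2 M t))`
(`work_energy_acceleration()`).

These two statements are only mutually consistent with the stride-mean
acceleration if `P_COM` is defined as the positive COM work of the *whole
stride* divided by the *hindlimb stroke duration*, and the hindlimb stroke
occupies about half the stride — which is exactly the footfall pattern of a
half-bound (forelimbs contact during the first half, hindlimbs during the
second). `com_power()` therefore accumulates positive energy increments over
the stride by default and divides by the hindlimb stroke duration; a
hindlimb-stance-only accumulation window is available via the `window`
argument for sensitivity analysis. On noiseless constant-acceleration
simulated trials both identities then hold to better than 2% and 5%
respectively (the residual coming from sampling the stance edges at 500 Hz).
The potential-energy term is included in `E` by default; a kinetic-only
variant is available (`include_pe = FALSE`), and the two coincide for level
trials.

## Marker smoothing

Digitized hip positions carry point-placement noise and occasional invisible
frames. Each axis is fit with a degree-5 (quintic) penalized B-spline with
one knot per frame and a 4th-order difference penalty on the coefficients.
The penalty's null space spans cubic trajectories — position histories with
smoothly varying acceleration — so noiseless cubic motion is reproduced to
machine precision while the derivative stays stable under noise.

The smoothing parameter is not user-tuned: it is set by bisection on
`log(lambda)` to the *largest* smoothing for which the residual criterion
still holds. The tolerance (default 0.75 mm^2) is interpreted as a bound on
the mean squared residual per visible frame; a total-SSR reading is
selectable via `tolerance_mode = "total"`. With 1 mm digitizing noise this
yields RMS residuals at or below the noise level and mid-stride velocity
errors under 5%; with 30% random dropout, interpolated positions stay within
2 mm of the true path. Fitting is per axis (the smoother never mixes axes),
and only the fore-aft and vertical (sagittal-plane) channels enter the
kinematic velocity profile.

## Stride segmentation

The stance threshold defaults to 2% of body weight. Raw thresholding is
fragile at realistic force noise (0.5 N against a ~0.2 N threshold for a
1 kg animal), so detection runs on a 5-sample moving average with a noise
floor of 4x the baseline MAD estimated from the first 40 ms of the trace;
above-threshold runs shorter than 10 ms are discarded, gaps shorter than
10 ms are bridged, and the retained interval edges are snapped back to the
raw threshold crossings. On noiseless traces this reduces exactly to raw
thresholding. All of these controls are arguments of `segment_stride()`.

## The synthetic study

There is no downloadable raw dataset bundled here, so the package carries a
generator whose defaults *are* the study conditions, and every downstream
stage is tested as parameter recovery against its known ground truth.

`simulate_trial()` emits physically consistent traces: fore-aft force equal
to `M_b * a(t)` over the stride (constant or half-sine profile; the
half-sine's stride mean is `2/pi` of its peak), vertical force balancing
body weight over stance (with optional flight phases), and marker positions
that are the exact double integral of the same accelerations from the true
initial velocity, sampled at 250 Hz with Gaussian noise and Bernoulli
dropout. Ground truth (`a_mean`, `v_esc`, `P_COM`, stride times, girdle
means) is computed from the noiseless signals by quadrature, independent of
the measurement pipeline under test. The default footfall is the half-bound
split: forelimb plate for the first half of the stride, hindlimb for the
second. Vertical dynamics are deliberately simplified (impulse-balanced
stance pulses); the pipeline needs physically consistent traces, not
biofidelic ones.

`simulate_cohort()` defaults encode the ontogenetic study design: 38
individuals (26 juveniles under the 1 kg cutoff, 12 adults) spanning
0.106-1.434 kg, five usable trials each; true mean acceleration quadratic in
mass with vertex at 0.74 kg and curvature -12 (m/s^2)/kg^2 (the curvature
implied by a ~1.6-fold juvenile:adult performance ratio at 0.8 vs 1.2 kg);
escape speed quadratic with vertex 0.82 kg; trial-to-trial repeatabilities
designed at ICC 0.359 (acceleration) and 0.537 (escape speed) through the
between/within variance split; acceleration and speed noise correlated at
0.8 (emulating the tight per-trial coupling of acceleration and final
speed, R^2 about 0.64); ten hindlimb extensor muscles per individual whose
architecture composes to `P_musc = 2.2 * M_b^1.32` W; per-trial COM power
derived from the work-energy relation; and survival durations linear in
standardized peak escape speed (default 20 days per SD against a 57-day
noise SD, i.e. a designed correlation near 0.33, with a 80-day baseline).

What the generator does *not* emulate: multi-stride trials, plate
cross-talk and calibration drift, non-Gaussian digitizing error, the full
empirical correlation matrix among the cohort metrics (the path-model R^2
partition on synthetic cohorts need not match any particular field
dataset), mass measurement error, or seasonal/sex structure. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to every field artifact.

## Statistical layer

**Quadratic performance-mass models.** At trial level, a random-intercept
mixed model (`nlme::lme`, maximum likelihood so AICc comparison against the
linear alternative is valid) with residual sd linear in mass. At peak level
(each rabbit's best trial), generalized least squares with the same variance
function, fit by a profiled ML: for a fixed variance-slope the problem is
weighted least squares, so the scalar profile is optimized directly. This
engine is equivalent to a constant-plus-power variance structure with the
power fixed at one, allows a negative slope (juveniles can be the noisier
group), and is fast enough to sit inside the case bootstrap; it is
cross-checked against `nlme::gls` in the test suite. Exactly noise-free
inputs are detected and fall back to OLS, since a degenerate residual
variance breaks GLS. AICc uses the number of trials (trial level) or
individuals (peak level) as its sample size; the mixed-model R^2 reported is
the marginal (fixed-effects) share of total variance.

**Vertex estimation.** The peak mass is `-b1 / (2 b2)` (requiring negative
curvature). Its CI is a case-resampling bootstrap with the individual as the
resampling unit (2000 draws by default, percentile interval, seed recorded);
resampled individuals keep all their trials and receive distinct ids so the
grouping structure is preserved. Ages come from a cubic-in-cube-root-of-mass
growth model. The published reference growth table is not redistributable,
so `growth_reference_synthetic()` builds a labelled synthetic stand-in
anchored at the reported mass-age pairs (0.74 kg at 94 d, 0.82 kg at 104 d,
1 kg at 133 d, neonate near zero); the growth model itself fits whatever
reference table it is given.

**Repeatability.** ICC is the between-individual variance share from a
random-intercept model (`lme4::lmer`), with a parametric-bootstrap CI. Note
that the raw-trial ICC of a cohort with a real mass trend exceeds the
designed noise-level ICC, because ontogenetic differences count as
between-individual variance; the designed value is recovered exactly when
the performance surface is flat, which is how the recovery tests are framed.

**Effect sizes.** Welch's t with Cohen's d on the pooled sd, categorized
(on |d|) at 0.2 / 0.5 / 0.8 / 1.2 / 2.0 for small / moderate / large / very
large / huge, anything lower being very small.

**Box-Cox and correlation.** `boxcox_z()` profiles the Box-Cox likelihood on
a fixed grid (lambda from -2 to 2 in steps of 0.01) and standardizes the
transformed values. One-tailed Pearson tests always test for a positive
association (the stated directional prediction). The Fisher-z power
approximation is `power = Phi(atanh(r) sqrt(n-3) - z_(1-alpha))`, inverted
and ceiled for required sample sizes. In the survival power analysis the
effect size enters at the two-decimal precision at which correlations are
conventionally reported; this matters because the required-n formula is
steep in `r` near small effects.

**Path analysis.** `fit_path()` estimates a recursive model over observed
z-scored variables by minimizing the ML discrepancy
`F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` with
`Sigma = (I - A)^-1 Psi (I - A)^-T` (free parameters: path coefficients,
endogenous residual variances on a log scale, exogenous variances and
covariances), using BFGS from a neutral start with a polishing restart.
Standard errors come from the observed information; `chisq = (n-1) F` at the
optimum, `RMSEA = sqrt(max(chisq - df, 0) / (df (n-1)))`, and CFI uses the
independence baseline (all variables uncorrelated). The `(n-1)` convention
is used throughout because the indices depend on it. For recursive models
the ML estimates must coincide with per-equation least squares; that
equivalence is asserted to 1e-6 in the tests. `prune()` removes the least
significant edge with p above alpha, one edge at a time (deterministic), and
refits; emptying all paths into an endogenous variable drops the variable
with a warning. The model is fit on raw (not mass-specific) COM power with
explicit mass edges; per-individual means are used at the cohort level,
matching the use of mean COM power as the individual's characteristic value.

**Scenarios.** From constant acceleration `a` at rest: distance in the first
second `a/2`; time to a refuge at `d` of `sqrt(2 d / a)`; strides to a top
speed `v` of `ceiling((v/a)/T_stride)`. The juvenile:adult distance ratio
and time ratio satisfy `distance_ratio * time_ratio^2 = 1` exactly. The
stride period is the one quantity theory does not fix; it defaults to twice
the mean hindlimb stroke duration of the processed dataset and makes the
stride-count scenario the most assumption-sensitive of the three.

## Muscle architecture chain

`PCSA = MM cos(theta) / (L_F rho)` with `rho = 1.06 g/cm^3`;
`F_max = 30 N/cm^2 * PCSA`; `V_max = 6.3` fascicle lengths per second
(fast-fiber value); `P_peak = 0.1 F_max V_max`; and
`P_musc = 2 * sum(P_peak)` over the ten sampled muscles/heads (both heads of
a two-headed muscle count as listed), the doubling representing simultaneous
bilateral hindlimb extension in the half-bound. Inputs stay in g/cm units so
the formulas read as conventionally printed; conversion to SI happens only
in the power step. Site-level pennation measurements are averaged as angles
first (cosine of the mean), matching the single-angle formula. A useful
composition law follows: `P_peak` is proportional to `MM` alone (the
fascicle lengths cancel between PCSA and `V_max`), so the allometric
exponent of `P_musc` equals that of muscle mass — geometric scaling
(`MM ~ M`, `L_F ~ M^(1/3)`) gives exactly 1.00.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on synthetic data at
these sizes, chosen to balance statistical resolution against desk-scale
runtimes: 100 noisy trials for pipeline recovery; 50 replicate cohorts (300
bootstrap draws each) for vertex-CI coverage; 100 individuals x 10 trials
for ICC recovery; n = 5000 for path-model coefficient recovery; 10 replicate
cohorts for the reported cohort-level quantities. Other conventions:
gravity 9.81 m/s^2; time re-based to the common trigger; fore-aft positive
in the direction of travel, vertical positive up; plates assumed zeroed with
an optional per-file baseline subtraction; a body mass of exactly 1.000 kg
classifies as adult; sampling is rejected if the time step varies by more
than 1 part in 1e3.

## Known limitations

The vertical-force model is a caricature (no double-peaked stance profiles,
no impact transients). Stance detection assumes an unloaded lead-in for its
noise floor. The path model handles observed variables only — no latent
factors, means, or groups. Survival is analyzed as a duration correlation,
not time-to-event regression. And all validation is against the synthetic
generator: agreement with any specific field dataset depends on how well
these simplifications describe it.
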