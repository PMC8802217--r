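#' @title Synthetic half-bound trial and cohort generators
#'
#' @description
#' Generators that emulate accelerative (burst) locomotion trials on a two-plate
#' runway and ontogenetic cohorts with known ground truth, so every downstream
#' stage of the pipeline has a parameter-recovery test. The trial generator
#' produces gravity-consistent force traces (fore-aft force = M_b * a(t) over
#' the stride, vertical force balancing body weight over stance) and marker
#' trajectories that are the exact double integral of the same accelerations,
#' with optional Gaussian noise and marker dropout. Vertical dynamics are
#' simplified (impulse-balanced stance pulses): the pipeline needs physically
#' consistent, not biofidelic, traces.
#'
#' @name burstloco-simulate
NULL

# run code under a temporary RNG state seeded with `seed`; restores the caller's
# stream afterwards so simulation calls are reproducible and side-effect free
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Parameters for one simulated trial
#'
#' @param body_mass body mass M_b (kg).
#' @param v0_true initial fore-aft COM velocity at stride onset (m/s).
#' @param profile acceleration profile family over the stride: `"constant"`
#'   (a(t) = a_mean) or `"halfsine"` (a(t) = a_peak sin(pi s/T), so the stride
#'   mean is 2/pi * a_peak).
#' @param a_mean target stride-mean fore-aft acceleration (m/s^2). For the
#'   half-sine family the peak is derived as `a_mean * pi / 2` unless `a_peak`
#'   is given.
#' @param a_peak optional explicit half-sine peak acceleration (m/s^2);
#'   overrides `a_mean`.
#' @param stride_duration stride duration T (s), onset of first contact to end
#'   of last contact.
#' @param fore_fraction fraction of the stride occupied by the forelimb
#'   (first-contacting) plate; the hindlimb plate carries the remainder. 0 puts
#'   the whole stride on the hindlimb plate.
#' @param stance_fraction fraction of each girdle's interval spent in contact
#'   (1 = continuous contact; < 1 inserts a flight phase with vertical force
#'   rescaled so the per-stride vertical impulse still balances gravity).
#' @param force_noise_sd,marker_noise_sd Gaussian noise sd on force samples (N)
#'   and marker coordinates (m).
#' @param marker_dropout probability a marker frame is invisible (in [0, 0.5)).
#' @param force_rate,marker_rate sampling rates (Hz); marker rate must divide
#'   the force rate.
#' @param lead_in,tail quiet time before stride onset and after stride end (s).
#' @param seed integer seed recorded in the output; NULL uses the current RNG
#'   stream.
#' @return A validated parameter list of class `trial_sim_params`.
#' @export
trial_sim_params <- function(body_mass = 0.8, v0_true = 0.1,
                             profile = c("halfsine", "constant"),
                             a_mean = 4, a_peak = NULL,
                             stride_duration = 0.25,
                             fore_fraction = 0.5, stance_fraction = 1,
                             force_noise_sd = 0, marker_noise_sd = 0,
                             marker_dropout = 0,
                             force_rate = 500, marker_rate = 250,
                             lead_in = 0.1, tail = 0.1, seed = NULL) {
  profile <- match.arg(profile)
  if (profile == "halfsine") {
    if (is.null(a_peak)) a_peak <- a_mean * pi / 2 else a_mean <- a_peak * 2 / pi
  }
  p <- list(body_mass = body_mass, v0_true = v0_true, profile = profile,
            a_mean = a_mean, a_peak = a_peak,
            stride_duration = stride_duration,
            fore_fraction = fore_fraction, stance_fraction = stance_fraction,
            force_noise_sd = force_noise_sd, marker_noise_sd = marker_noise_sd,
            marker_dropout = marker_dropout,
            force_rate = force_rate, marker_rate = marker_rate,
            lead_in = lead_in, tail = tail, seed = seed)
  if (body_mass <= 0) stop("validation error: body_mass must be > 0")
  if (stride_duration <= 0 || lead_in < 0 || tail < 0) {
    stop("validation error: durations must be positive")
  }
  if (force_noise_sd < 0 || marker_noise_sd < 0) {
    stop("validation error: noise sds must be >= 0")
  }
  if (marker_dropout < 0 || marker_dropout > 0.5) {
    stop("validation error: marker dropout probability must lie in [0, 0.5]")
  }
  if (fore_fraction < 0 || fore_fraction >= 1) {
    stop("validation error: fore_fraction must lie in [0, 1)")
  }
  if (stance_fraction <= 0 || stance_fraction > 1) {
    stop("validation error: stance_fraction must lie in (0, 1]")
  }
  if (force_rate %% marker_rate != 0) {
    stop("validation error: marker rate must divide force rate")
  }
  class(p) <- "trial_sim_params"
  p
}

# cumulative trapezoidal integral, same length as y, starting at 0
cumtrapz <- function(t, y) {
  n <- length(y)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

#' Simulate one burst trial with known ground truth
#'
#' The noiseless fore-aft trace encodes exactly the requested stride-mean
#' acceleration (trapezoidal integral of F_FA over the stride equals
#' `M_b * a_mean * T`), marker positions are the cumulative trapezoidal double
#' integral of the same accelerations from `v0_true`, and the recorded ground
#' truth (`a_mean`, `v_esc`, `P_COM`, girdle means, stride times) is computed
#' from those noiseless signals by quadrature — independent of the measurement
#' pipeline under test.
#'
#' @param params a [trial_sim_params()] list.
#' @param trial_id,rabbit_id,collar identifiers passed to the bundle.
#' @return List with elements `bundle` (a [trial_bundle()]) and `truth`
#'   (named list: `a_mean`, `v0`, `v_esc`, `t0`, `t_end`, `stroke`,
#'   `fore_a`, `hind_a`, `p_com`, `seed`).
#' @export
simulate_trial <- function(params = trial_sim_params(), trial_id = "sim1",
                           rabbit_id = "r1", collar = FALSE) {
  stopifnot(inherits(params, "trial_sim_params"))
  p <- params
  g <- 9.81
  dt <- 1 / p$force_rate
  total <- p$lead_in + p$stride_duration + p$tail
  time <- seq(0, total, by = dt)
  t0 <- p$lead_in
  t_end <- t0 + p$stride_duration
  Td <- p$stride_duration
  s <- time - t0

  # instantaneous fore-aft acceleration a(t) on the closed stride window, so
  # the trapezoidal integral of F_FA over [t0, t_end] encodes the requested
  # impulse exactly for the constant profile (the half-sine vanishes at both
  # edges and is quadrature-exact to O(dt^2))
  in_stride <- time >= t0 - dt / 4 & time <= t_end + dt / 4
  a_fa <- numeric(length(time))
  if (p$profile == "constant") {
    a_fa[in_stride] <- p$a_mean
  } else {
    a_fa[in_stride] <- p$a_peak * sin(pi * pmin(pmax(s[in_stride], 0), Td) / Td)
  }

  # girdle split: forelimb plate takes the first fore_fraction of the stride
  t_split <- t0 + p$fore_fraction * Td
  fore_idx <- in_stride & time < t_split - dt / 4
  hind_idx <- in_stride & !fore_idx

  # stance sub-intervals (flight inserted at the end of each girdle interval);
  # forces rescaled by 1/stance_fraction so girdle impulses are preserved
  sf <- p$stance_fraction
  stance <- function(idx) {
    tt <- time[idx]
    if (!length(tt)) return(logical(0))
    span <- max(tt) + dt - min(tt)
    tt < min(tt) + sf * span - dt / 4
  }
  f_fa_t <- a_fa * p$body_mass
  f_v_t <- numeric(length(time))
  for (idx in list(fore_idx, hind_idx)) {
    if (!any(idx)) next
    st <- stance(idx)
    f_fa_t[idx][!st] <- 0
    f_fa_t[idx][st] <- f_fa_t[idx][st] / sf
    f_v_t[idx][st] <- p$body_mass * g / sf
  }

  # true COM kinematics from the (noiseless, possibly rescaled) traces
  a_inst <- f_fa_t / p$body_mass
  v_fa <- p$v0_true + cumtrapz(time, a_inst)
  x <- 0.3 + cumtrapz(time, v_fa)
  a_v <- ifelse(in_stride, f_v_t / p$body_mass - g, 0)
  v_v <- cumtrapz(time, a_v)
  z <- 0.07 + cumtrapz(time, v_v)

  impulse <- cumtrapz(time, f_fa_t)
  win <- function(idx) {   # trapezoidal mean of F_FA / M over a sample window
    i0 <- min(which(idx)); i1 <- max(which(idx))
    (impulse[i1] - impulse[i0]) / (p$body_mass * (time[i1] - time[i0]))
  }
  true_a <- win(in_stride)
  true_vesc <- p$v0_true + true_a * Td
  girdle_mean <- function(idx) if (any(idx)) win(idx) else NA_real_
  stance_span <- function(idx) {
    tt <- time[idx][stance(idx)]
    max(tt) - min(tt)
  }
  stroke <- if (any(hind_idx)) stance_span(hind_idx) else stance_span(fore_idx)

  # true COM power: positive increments of E = KE + PE over the stride,
  # divided by the hindlimb stroke duration
  # within-stride COM energy, velocity re-based so v(t0) = v0 exactly
  i0 <- min(which(in_stride))
  v_str <- p$v0_true + (impulse[in_stride] - impulse[i0]) / p$body_mass
  E <- 0.5 * p$body_mass * (v_str^2 + v_v[in_stride]^2) +
    p$body_mass * g * (z[in_stride] - z[i0])
  dE <- diff(E)
  true_pcom <- sum(dE[dE > 0]) / stroke

  out <- with_seed(p$seed, {
    # two plates, each recording the full time base
    f1_fa <- ifelse(fore_idx, f_fa_t, 0)
    f1_v <- ifelse(fore_idx, f_v_t, 0)
    f2_fa <- ifelse(hind_idx, f_fa_t, 0)
    f2_v <- ifelse(hind_idx, f_v_t, 0)
    if (p$force_noise_sd > 0) {
      f1_fa <- f1_fa + stats::rnorm(length(time), 0, p$force_noise_sd)
      f1_v <- f1_v + stats::rnorm(length(time), 0, p$force_noise_sd)
      f2_fa <- f2_fa + stats::rnorm(length(time), 0, p$force_noise_sd)
      f2_v <- f2_v + stats::rnorm(length(time), 0, p$force_noise_sd)
    }
    force <- force_trace(rep(time, 2), rep(c(1L, 2L), each = length(time)),
                         c(f1_fa, f2_fa), c(f1_v, f2_v))

    step <- p$force_rate / p$marker_rate
    mi <- seq(1L, length(time), by = step)
    mx <- x[mi]; my <- rep(0, length(mi)); mz <- z[mi]
    if (p$marker_noise_sd > 0) {
      mx <- mx + stats::rnorm(length(mi), 0, p$marker_noise_sd)
      my <- my + stats::rnorm(length(mi), 0, p$marker_noise_sd)
      mz <- mz + stats::rnorm(length(mi), 0, p$marker_noise_sd)
    }
    visible <- stats::runif(length(mi)) >= p$marker_dropout
    if (mean(!visible) >= 0.5) visible[!visible][seq_len(ceiling(length(mi) / 2))] <- TRUE
    mx[!visible] <- NA; my[!visible] <- NA; mz[!visible] <- NA
    markers <- marker_trajectory(time[mi], mx, my, mz, visible)
    trial_bundle(trial_id, rabbit_id, p$body_mass, force, markers, collar)
  })

  list(bundle = out,
       truth = list(a_mean = true_a, v0 = p$v0_true, v_esc = true_vesc,
                    t0 = t0, t_end = t_end, stroke = stroke,
                    fore_a = girdle_mean(fore_idx), hind_a = girdle_mean(hind_idx),
                    p_com = true_pcom, seed = p$seed))
}

# force_trace with plate column where each plate spans the full time base:
# split long-format rows back into synchronized per-plate series
split_plates <- function(force) {
  lapply(split(seq_len(nrow(force)), force$plate), function(i) force[i, ])
}

#' Parameters for a simulated ontogenetic cohort
#'
#' Defaults emulate the study conditions of an ontogenetic cottontail sample:
#' 38 individuals spanning 0.106-1.434 kg (so roughly two-thirds fall under
#' the 1 kg juvenile cutoff), about 5 usable trials per individual, peak
#' acceleration quadratic in mass with vertex at 0.74 kg, escape-speed vertex
#' at 0.82 kg, trial-to-trial repeatabilities (ICC) of 0.359 and 0.537,
#' hindlimb extensor power scaling as 2.2 * M^1.32 W, and survival durations
#' with a tunable dependence on standardized peak escape speed.
#'
#' @param n_individuals number of individuals (>= 3).
#' @param n_juvenile number of individuals drawn below the 1 kg juvenile
#'   cutoff; defaults to the 26-of-38 composition scaled to `n_individuals`.
#' @param mass_range body-mass range (kg), sampled uniformly within each age
#'   class.
#' @param trials_per_individual usable trials per individual.
#' @param a_vertex_mass,a_vertex_value,a_curvature quadratic for true
#'   individual-mean acceleration (m/s^2): value + curvature * (M - vertex)^2,
#'   curvature < 0.
#' @param a_between_sd,a_within_sd between- and within-individual sd of trial
#'   acceleration (m/s^2); designed ICC = between^2 / (between^2 + within^2).
#' @param v_vertex_mass,v_vertex_value,v_curvature,v_between_sd,v_within_sd
#'   same for escape speed (m/s).
#' @param av_correlation correlation between the acceleration and escape-speed
#'   noise components (both between and within individuals), emulating the
#'   tight per-trial coupling of acceleration and final speed (about r = 0.8,
#'   i.e. R^2 near 0.64).
#' @param muscle_coef,muscle_exponent total hindlimb extensor power capacity
#'   P_musc = coef * M^exponent (W) at zero noise; 1.0 is geometric and 1.33
#'   mechanical similarity.
#' @param muscle_sd_dex per-individual lognormal scatter (sd of log10) on
#'   muscle masses.
#' @param lf_exponent allometric exponent of fascicle length on mass.
#' @param v0_range per-trial initial velocity range (m/s).
#' @param stroke_mean,stroke_sd hindlimb stroke duration distribution (s).
#' @param collar_prob probability an individual is radio-collared.
#' @param survival_baseline,survival_effect,survival_sd survival duration
#'   (days) = baseline + effect * z(peak v_esc) + N(0, sd), floored at 1;
#'   effect = 0 gives the null model.
#' @param seed integer seed.
#' @return Parameter list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_individuals = 38, n_juvenile = NULL,
                              mass_range = c(0.106, 1.434),
                              trials_per_individual = 5,
                              a_vertex_mass = 0.74, a_vertex_value = 6.5,
                              a_curvature = -12,
                              a_between_sd = sqrt(0.359), a_within_sd = sqrt(0.641),
                              v_vertex_mass = 0.82, v_vertex_value = 2.0,
                              v_curvature = -1.5,
                              v_between_sd = sqrt(0.537 * 0.1225),
                              v_within_sd = sqrt(0.463 * 0.1225),
                              av_correlation = 0.8,
                              muscle_coef = 2.2, muscle_exponent = 1.32,
                              muscle_sd_dex = 0.06, lf_exponent = 1 / 3,
                              v0_range = c(0, 0.3),
                              stroke_mean = 0.125, stroke_sd = 0.015,
                              collar_prob = 0.58,
                              survival_baseline = 80, survival_effect = 20,
                              survival_sd = 57,
                              seed = NULL) {
  p <- as.list(environment())
  if (is.null(n_juvenile)) {
    p$n_juvenile <- round(n_individuals * 26 / 38)   # study composition
  }
  if (n_individuals < 3) stop("validation error: need at least 3 individuals")
  if (p$n_juvenile < 0 || p$n_juvenile > n_individuals) {
    stop("validation error: n_juvenile must lie in [0, n_individuals]")
  }
  if (a_curvature >= 0 || v_curvature >= 0) {
    stop("validation error: curvature must be negative (inverted parabola)")
  }
  if (any(c(a_between_sd, a_within_sd, v_between_sd, v_within_sd,
            muscle_sd_dex, stroke_sd, survival_sd) < 0)) {
    stop("validation error: sds must be >= 0")
  }
  if (abs(av_correlation) > 1) {
    stop("validation error: av_correlation must lie in [-1, 1]")
  }
  class(p) <- "cohort_sim_params"
  p
}

# reference hindlimb extensor set: relative belly masses (g at 1 kg body mass,
# before rescaling to the requested power coefficient), fascicle lengths (cm at
# 1 kg) and representative pennation angles (deg)
.muscle_base <- function() {
  data.frame(
    muscle = c("m. gluteus profundus", "m. gluteus medialis",
               "m. biceps femoris (vertebral head)",
               "m. biceps femoris (pelvic head)", "m. semimembranosus",
               "m. vastus lateralis", "m. rectus femoris",
               "m. gastrocnemius (lateral head)",
               "m. gastrocnemius (medial head)", "m. soleus"),
    group = c(rep("hip", 5), rep("knee", 2), rep("ankle", 3)),
    mm_rel = c(0.8, 1.6, 1.4, 1.0, 0.9, 1.2, 0.8, 0.7, 0.6, 0.15),
    lf_rel = c(1.6, 1.8, 3.0, 2.8, 2.6, 1.9, 2.2, 1.3, 1.2, 1.0),
    theta_deg = c(10, 12, 5, 5, 8, 15, 10, 20, 20, 8))
}

#' Simulate an ontogenetic cohort with known ground truth
#'
#' Per-individual true means follow the specified quadratics in body mass;
#' per-trial values add within-individual noise (so the designed ICC is
#' between-variance / total variance); muscle tables scale allometrically so
#' the architecturally derived P_musc follows `coef * M^exponent`; survival
#' durations follow the stated linear model in standardized peak escape speed.
#'
#' @param params a [cohort_sim_params()] list.
#' @return List with data frames `cohort` (one row per individual: ids, mass,
#'   age class, collar status, survival, true means), `trials` (per-trial
#'   performance metrics), `muscles` (per-individual architecture table), and
#'   `truth` (the generating parameters).
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  with_seed(p$seed, {
    id <- sprintf("R%02d", seq_len(p$n_individuals))
    # stratified by age class: juveniles below the 1 kg cutoff, adults above
    cut_j <- min(1, p$mass_range[2])
    mass <- sort(c(stats::runif(p$n_juvenile, p$mass_range[1], min(0.999, cut_j)),
                   stats::runif(p$n_individuals - p$n_juvenile,
                                max(1.0, p$mass_range[1]), p$mass_range[2])))
    quad <- function(m, vm, vv, cc) vv + cc * (m - vm)^2
    # correlated noise components: individuals (and trials) that accelerate
    # harder also exit faster
    rho <- p$av_correlation
    eb_a <- stats::rnorm(p$n_individuals)
    eb_v <- rho * eb_a + sqrt(1 - rho^2) * stats::rnorm(p$n_individuals)
    a_ind <- quad(mass, p$a_vertex_mass, p$a_vertex_value, p$a_curvature) +
      p$a_between_sd * eb_a
    v_ind <- quad(mass, p$v_vertex_mass, p$v_vertex_value, p$v_curvature) +
      p$v_between_sd * eb_v

    k <- p$trials_per_individual
    n_tr <- p$n_individuals * k
    trials <- data.frame(
      rabbit_id = rep(id, each = k),
      trial = paste0(rep(id, each = k), "_t", rep(seq_len(k), p$n_individuals)),
      body_mass_kg = rep(mass, each = k))
    ew_a <- stats::rnorm(n_tr)
    ew_v <- rho * ew_a + sqrt(1 - rho^2) * stats::rnorm(n_tr)
    trials$a_com <- rep(a_ind, each = k) + p$a_within_sd * ew_a
    trials$v_esc <- rep(v_ind, each = k) + p$v_within_sd * ew_v
    trials$v0 <- stats::runif(n_tr, p$v0_range[1], p$v0_range[2])
    trials$stroke_s <- pmax(0.05, stats::rnorm(n_tr, p$stroke_mean, p$stroke_sd))
    # work-energy-consistent COM power for the stride behind each trial
    trials$p_com <- 0.5 * trials$body_mass_kg *
      pmax(0.1, trials$v_esc)^2 / trials$stroke_s
    trials$p_com_per_kg <- trials$p_com / trials$body_mass_kg

    base <- .muscle_base()
    p_per_g <- 2 * 0.1 * 30 * 0.063 / 1.06    # W per (g of cos-weighted mass)
    scale0 <- p$muscle_coef / (p_per_g * sum(base$mm_rel * cos(base$theta_deg * pi / 180)))
    muscles <- do.call(rbind, lapply(seq_len(p$n_individuals), function(i) {
      jitter <- 10^stats::rnorm(1, 0, p$muscle_sd_dex)
      data.frame(rabbit_id = id[i], muscle = base$muscle,
                 mm_g = base$mm_rel * scale0 * mass[i]^p$muscle_exponent * jitter,
                 lf_cm = base$lf_rel * mass[i]^p$lf_exponent,
                 theta_deg = base$theta_deg)
    }))

    peak_v <- tapply(trials$v_esc, trials$rabbit_id, max)[id]
    zsurv <- as.numeric(scale(peak_v))
    collared <- stats::runif(p$n_individuals) < p$collar_prob
    survival <- pmax(1, p$survival_baseline + p$survival_effect * zsurv +
                       stats::rnorm(p$n_individuals, 0, p$survival_sd))
    survival[!collared] <- NA

    cohort <- data.frame(rabbit_id = id, body_mass_kg = mass,
                         age_class = age_class(mass), collared = collared,
                         survival_days = survival,
                         true_mean_a = a_ind, true_mean_v = v_ind)
    list(cohort = cohort, trials = trials, muscles = muscles, truth = p)
  })
}
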