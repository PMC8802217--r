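test_that("constant-acceleration trials encode the stated force and speed", {
  s <- simulate_trial(trial_sim_params(body_mass = 1, v0_true = 0,
                                       profile = "constant", a_mean = 4,
                                       stride_duration = 0.25,
                                       fore_fraction = 0, seed = 1))
  f <- s$bundle$force
  hind <- f[f$plate == 2L, ]
  in_stride <- hind$time >= 0.1 - 1e-9 & hind$time <= 0.35 + 1e-9
  expect_true(all(abs(hind$f_fa[in_stride] - 4) < 1e-12))
  expect_true(all(hind$f_fa[!in_stride] == 0))
  expect_equal(s$truth$v_esc, 1.0, tolerance = 1e-9)
  expect_equal(s$truth$a_mean, 4, tolerance = 1e-9)

  s2 <- simulate_trial(trial_sim_params(body_mass = 1, v0_true = 0.5,
                                        profile = "constant", a_mean = 4,
                                        stride_duration = 0.25, seed = 1))
  expect_equal(s2$truth$v_esc, 1.5, tolerance = 1e-9)   # v0 adds linearly
})

test_that("half-sine pulses average to 2/pi of the peak (quadrature check)", {
  s <- simulate_trial(trial_sim_params(body_mass = 1, a_peak = 6,
                                       profile = "halfsine", seed = 2))
  expect_equal(s$truth$a_mean, 6 * 2 / pi, tolerance = 1e-3)
  # independent quadrature of the emitted trace over the stride
  f <- s$bundle$force
  tot <- aggregate(f_fa ~ time, f, sum)
  sel <- tot$time >= s$truth$t0 - 1e-9 & tot$time <= s$truth$t_end + 1e-9
  imp <- trapz_ref(tot$time[sel], tot$f_fa[sel])
  expect_equal(imp / (s$truth$t_end - s$truth$t0), s$truth$a_mean,
               tolerance = 1e-9)
})

test_that("noiseless trace impulse always reproduces the true escape speed", {
  for (prof in c("constant", "halfsine")) {
    for (sd in c(0.2, 0.35)) {
      p <- trial_sim_params(body_mass = 0.7, v0_true = 0.25, profile = prof,
                            a_mean = 5, stride_duration = sd, seed = 3)
      s <- simulate_trial(p)
      f <- s$bundle$force
      tot <- aggregate(f_fa ~ time, f, sum)
      sel <- tot$time >= s$truth$t0 - 1e-9 & tot$time <= s$truth$t_end + 1e-9
      v <- trapz_ref(tot$time[sel], tot$f_fa[sel]) / 0.7 + 0.25
      expect_equal(v, s$truth$v_esc, tolerance = 1e-6)
    }
  }
})

test_that("vertical force balances gravity over the stride", {
  for (sf in c(1, 0.7)) {
    s <- simulate_trial(trial_sim_params(body_mass = 0.9, stance_fraction = sf,
                                         seed = 4))
    f <- s$bundle$force
    tot <- aggregate(f_v ~ time, f, sum)
    sel <- tot$time >= s$truth$t0 - 1e-9 & tot$time <= s$truth$t_end + 1e-9
    imp <- trapz_ref(tot$time[sel], tot$f_v[sel])
    expect_equal(imp, 0.9 * 9.81 * (s$truth$t_end - s$truth$t0),
                 tolerance = 0.02 * imp)
  }
})

test_that("simulation parameters are validated", {
  expect_error(trial_sim_params(marker_dropout = 0.6), "dropout")
  expect_error(trial_sim_params(stride_duration = -1), "durations")
  expect_error(trial_sim_params(force_noise_sd = -1), "noise")
  expect_error(cohort_sim_params(n_individuals = 2), "at least 3")
  expect_error(cohort_sim_params(a_curvature = 0.5), "curvature")
  expect_error(cohort_sim_params(a_within_sd = -1), "sds")
})

test_that("geometric muscle scaling yields a power exponent of one", {
  co <- simulate_cohort(cohort_sim_params(n_individuals = 50, n_juvenile = 34,
                                          muscle_exponent = 1.0,
                                          lf_exponent = 1 / 3,
                                          muscle_sd_dex = 0.02, seed = 5))
  pm <- muscle_power_table(co$muscles)
  m <- co$cohort$body_mass_kg[match(pm$rabbit_id, co$cohort$rabbit_id)]
  fit <- fit_allometry(pm$p_musc_W, m)
  expect_lt(abs(fit$exponent - 1.00), 0.02)
})

test_that("a zero survival effect leaves speed and survival uncorrelated", {
  rs <- vapply(1:12, function(i) {
    co <- simulate_cohort(cohort_sim_params(survival_effect = 0,
                                            collar_prob = 1, seed = 600 + i))
    pk <- tapply(co$trials$v_esc, co$trials$rabbit_id, max)
    stats::cor(pk[co$cohort$rabbit_id], co$cohort$survival_days)
  }, 0)
  expect_lt(abs(mean(rs)), 0.12)   # centred on zero across seeds
})

test_that("the designed ICC is recovered from simulated trials", {
  # flat performance surface so the between/within decomposition is the only
  # source of individual differences
  co <- simulate_cohort(cohort_sim_params(
    n_individuals = 100, n_juvenile = 68, trials_per_individual = 10,
    a_vertex_value = 5, a_curvature = -1e-9,
    a_between_sd = sqrt(0.359), a_within_sd = sqrt(0.641), seed = 7))
  icc <- repeatability_icc(data.frame(rabbit_id = co$trials$rabbit_id,
                                      value = co$trials$a_com), n_boot = 0)
  expect_lt(abs(icc$icc - 0.359), 0.05)
})
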