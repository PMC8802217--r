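test_that("stride segmentation finds stance windows and girdle assignment", {
  # all-zero trace: nothing to segment
  zero <- boxcar_trace(0, 0)
  expect_error(segment_stride(zero, body_mass = 1), "no-stride")

  # single stance pulse 0.10-0.35 s
  seg <- segment_stride(boxcar_trace(4, 9.81), body_mass = 1)
  expect_lt(abs(seg$t0 - 0.10), 0.0021)
  expect_lt(abs(seg$t_end - 0.35), 0.0021)
  expect_equal(seg$stances$girdle, "hind")   # single contact = hindlimb

  # two plates, fore contact first
  s <- simulate_trial(trial_sim_params(body_mass = 0.8, fore_fraction = 0.5,
                                       seed = 21))
  seg2 <- segment_stride(s$bundle$force, body_mass = 0.8)
  expect_equal(seg2$fore_plate, "1")
  expect_equal(seg2$hind_plate, "2")
  expect_lt(abs(seg2$stroke - s$truth$stroke), 0.005)
})

test_that("mean acceleration is the force-mass quotient", {
  seg <- segment_stride(boxcar_trace(8, 9.81), body_mass = 1)
  expect_equal(mean_acceleration(seg, boxcar_trace(8, 9.81), 1), 8,
               tolerance = 1e-9)
  expect_equal(mean_acceleration(seg, boxcar_trace(0, 9.81), 1), 0)
  # half-sine trial: matches the true mean within 1%
  s <- simulate_trial(trial_sim_params(body_mass = 0.9, a_mean = 6, seed = 22))
  seg2 <- segment_stride(s$bundle$force, body_mass = 0.9)
  expect_lt(abs(mean_acceleration(seg2, s$bundle$force, 0.9) - 6) / 6, 0.01)
})

test_that("escape speed integrates the fore-aft impulse", {
  tr <- boxcar_trace(5, 9.81, on = 0.10, off = 0.30)
  seg <- segment_stride(tr, body_mass = 1)
  expect_equal(escape_speed(seg, tr, 1, v0 = 0.5), 1.5, tolerance = 1e-9)
  expect_equal(escape_speed(seg, boxcar_trace(0, 9.81, on = 0.10, off = 0.30),
                            1, v0 = 0), 0)
  # noiseless synthetic trial reproduces truth to 1e-4 m/s
  s <- simulate_trial(trial_sim_params(body_mass = 0.8, v0_true = 0.3, seed = 23))
  seg2 <- segment_stride(s$bundle$force, body_mass = 0.8)
  expect_lt(abs(escape_speed(seg2, s$bundle$force, 0.8, 0.3) - s$truth$v_esc),
            1e-4)
})

test_that("v0 optimization is exact, linear, and robust to noise", {
  s <- simulate_trial(trial_sim_params(body_mass = 1, v0_true = 0, seed = 24))
  tr <- s$bundle$force
  seg <- segment_stride(tr, body_mass = 1)
  # kinematic profile manufactured from the kinetic one with v0 = 0.3
  tot <- aggregate(f_fa ~ time, tr, sum)
  sel <- tot$time >= seg$t0 & tot$time <= seg$t_end
  tt <- tot$time[sel]
  vi <- 0.3 + cumsum(c(0, diff(tt) * (tot$f_fa[sel][-1] + tot$f_fa[sel][-sum(sel)]) / 2))
  prof <- data.frame(time = tt, v_fa = vi)
  o <- optimize_v0(seg, tr, 1, prof, v0_seed = 0.3)
  expect_lt(abs(o$v0 - 0.3), 1e-9)
  expect_lt(abs(o$v0_iter - o$v0), 1e-6)
  # offsetting the kinematic profile shifts v0 by exactly the offset
  prof2 <- transform(prof, v_fa = v_fa + 0.2)
  expect_equal(optimize_v0(seg, tr, 1, prof2, 0.5)$v0, o$v0 + 0.2,
               tolerance = 1e-9)
  # noisy marker route stays within 0.05 m/s
  s2 <- simulate_trial(trial_sim_params(body_mass = 0.8, v0_true = 0.25,
                                        marker_noise_sd = 1e-3, seed = 25))
  r <- process_trial(s2$bundle)
  expect_lt(abs(r$v0 - 0.25), 0.05)
})

test_that("COM power follows the work-energy theorem", {
  # constant force, level COM, single hindlimb stance covering the stride:
  # dE = 0.5 J over 0.25 s
  s <- simulate_trial(trial_sim_params(body_mass = 1, v0_true = 0,
                                       profile = "constant", a_mean = 4,
                                       stride_duration = 0.25,
                                       fore_fraction = 0, seed = 26))
  seg <- segment_stride(s$bundle$force, body_mass = 1)
  expect_equal(com_power(seg, s$bundle$force, 1, 0), 2.0, tolerance = 0.01)
  # zero net fore-aft force: no energy fluctuation
  tr0 <- boxcar_trace(0, 9.81)
  seg0 <- segment_stride(tr0, body_mass = 1)
  expect_equal(com_power(seg0, tr0, 1, 0), 0, tolerance = 1e-9)
  # with level motion P_COM equals dKE / stroke
  s2 <- simulate_trial(trial_sim_params(body_mass = 0.8, v0_true = 0.2, seed = 27))
  seg2 <- segment_stride(s2$bundle$force, body_mass = 0.8)
  p <- com_power(seg2, s2$bundle$force, 0.8, 0.2)
  vesc <- escape_speed(seg2, s2$bundle$force, 0.8, 0.2)
  dke <- 0.5 * 0.8 * (vesc^2 - 0.2^2)
  expect_equal(p, dke / seg2$stroke, tolerance = 0.02)
})

test_that("the work-energy acceleration relation inverts cleanly", {
  expect_equal(work_energy_acceleration(8, 1, 0.25), 4)
  expect_equal(work_energy_acceleration(32, 1, 0.25),
               2 * work_energy_acceleration(8, 1, 0.25))
  set.seed(28)
  for (i in 1:20) {
    a <- runif(1, 1, 10); m <- runif(1, 0.2, 2); t <- runif(1, 0.05, 0.4)
    expect_equal(work_energy_acceleration(2 * m * t * a^2, m, t), a,
                 tolerance = 1e-12)
  }
  expect_error(work_energy_acceleration(-1, 1, 1), "domain error")
})

test_that("girdle accelerations decompose the stride", {
  # symmetric fore/hind pulses on a constant-acceleration trial
  s <- simulate_trial(trial_sim_params(body_mass = 1, profile = "constant",
                                       a_mean = 5, fore_fraction = 0.5,
                                       seed = 29))
  seg <- segment_stride(s$bundle$force, body_mass = 1)
  ga <- girdle_accelerations(seg, s$bundle$force, 1)
  expect_equal(unname(ga["fore_a"]), unname(ga["hind_a"]), tolerance = 1e-6)
  expect_equal(unname(ga["hind_a"]), 5, tolerance = 1e-6)

  # hind pulse twice the fore pulse: construct a two-level boxcar
  tt <- seq(0, 0.45, by = 0.002)
  lev <- ifelse(tt >= 0.1 & tt < 0.225, 3, ifelse(tt >= 0.225 & tt <= 0.35, 6, 0))
  fv <- ifelse(tt >= 0.1 & tt <= 0.35, 9.81, 0)
  plate <- ifelse(tt < 0.225, 1L, 2L)
  tr <- force_trace(rep(tt, 2), rep(c(1L, 2L), each = length(tt)),
                    c(ifelse(plate == 1L, lev, 0), ifelse(plate == 2L, lev, 0)),
                    c(ifelse(plate == 1L, fv, 0), ifelse(plate == 2L, fv, 0)))
  seg2 <- segment_stride(tr, body_mass = 1)
  ga2 <- girdle_accelerations(seg2, tr, 1)
  expect_equal(unname(ga2["hind_a"] / ga2["fore_a"]), 2, tolerance = 1e-6)

  # duration-weighted girdle means recompose the whole-stride mean
  w_fore <- diff(unlist(seg2$stances[seg2$stances$girdle == "fore", c("on", "off")]))
  w_hind <- diff(unlist(seg2$stances[seg2$stances$girdle == "hind", c("on", "off")]))
  acom <- mean_acceleration(seg2, tr, 1)
  recomposed <- (ga2["fore_a"] * w_fore + ga2["hind_a"] * w_hind) /
    (seg2$t_end - seg2$t0)
  expect_equal(unname(recomposed), acom, tolerance = 0.05 * acom)
})

test_that("impulse-velocity consistency holds on every trial", {
  for (i in 1:5) {
    s <- simulate_trial(trial_sim_params(body_mass = 0.6 + 0.1 * i,
                                         v0_true = 0.05 * i, a_mean = 2 + i,
                                         force_noise_sd = 0.3,
                                         marker_noise_sd = 5e-4,
                                         seed = 300 + i))
    M <- 0.6 + 0.1 * i
    seg <- segment_stride(s$bundle$force, body_mass = M)
    a <- mean_acceleration(seg, s$bundle$force, M)
    v0 <- 0.05 * i
    vesc <- escape_speed(seg, s$bundle$force, M, v0)
    expect_equal(vesc - v0, a * (seg$t_end - seg$t0), tolerance = 1e-6)
  }
})

test_that("the full pipeline recovers simulated ground truth", {
  errs <- t(vapply(1:20, function(i) {
    set.seed(4000 + i)
    p <- trial_sim_params(body_mass = runif(1, 0.4, 1.4),
                          v0_true = runif(1, 0, 0.4),
                          a_mean = runif(1, 2, 8),
                          force_noise_sd = 0.5, marker_noise_sd = 1e-3,
                          marker_dropout = 0.05, seed = 4000 + i)
    s <- simulate_trial(p)
    r <- process_trial(s$bundle)
    c(abs(r$a_com - s$truth$a_mean) / s$truth$a_mean,
      abs(r$v0 - s$truth$v0),
      abs(r$v_esc - s$truth$v_esc) / abs(s$truth$v_esc))
  }, numeric(3)))
  expect_lt(median(errs[, 1]), 0.03)
  expect_lt(median(errs[, 2]), 0.05)
  expect_lt(median(errs[, 3]), 0.03)
})
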