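test_that("an exact parabola is recovered to machine precision", {
  m <- seq(0.2, 1.4, length.out = 20)
  d <- data.frame(mass = m, response = 5 - 6 * (m - 0.74)^2,
                  rabbit_id = paste0("r", seq_along(m)))
  f <- fit_quadratic(d, "peak")
  expect_equal(c(f$b0, f$b1, f$b2),
               c(5 - 6 * 0.74^2, 12 * 0.74, -6), tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  v <- vertex(f, n_boot = 50, seed = 1)
  expect_equal(v$peak_mass, 0.74, tolerance = 1e-8)
  expect_true(v$mass_ci[1] <= 0.74 && 0.74 <= v$mass_ci[2])
})

test_that("model comparison prefers the correct curvature", {
  set.seed(2)
  m <- runif(40, 0.2, 1.4)
  lin <- data.frame(mass = m, response = 1 + 2 * m + rnorm(40, 0, 0.2),
                    rabbit_id = paste0("r", 1:40))
  fl <- fit_quadratic(lin, "peak")
  expect_lt(fl$aicc["linear"], fl$aicc["quadratic"])

  dat <- cohort_quad_data(seed = 33)
  fq_peak <- fit_quadratic(dat$a, "peak")
  fq_trial <- fit_quadratic(dat$a, "trial")
  expect_lt(fq_peak$aicc["quadratic"], fq_peak$aicc["linear"])
  expect_lt(fq_trial$aicc["quadratic"], fq_trial$aicc["linear"])
  expect_lt(fq_trial$b2, 0)
})

test_that("AICc prefers the quadratic under strong curvature across seeds", {
  wins <- vapply(1:10, function(i) {
    set.seed(40 + i)
    m <- runif(30, 0.2, 1.4)
    d <- data.frame(mass = m, response = 6 - 6 * (m - 0.74)^2 + rnorm(30, 0, 0.3),
                    rabbit_id = paste0("r", 1:30))
    f <- fit_quadratic(d, "peak")
    f$aicc["quadratic"] <= f$aicc["linear"]
  }, TRUE)
  expect_true(all(wins))
})

test_that("the vertex estimator is shift-equivariant and covers truth", {
  dat <- cohort_quad_data(seed = 34)
  f <- fit_quadratic(dat$a, "peak")
  v <- vertex(f, n_boot = 100, seed = 3)
  shifted <- dat$a; shifted$mass <- shifted$mass + 0.5
  f2 <- fit_quadratic(shifted, "peak")
  expect_equal(-f2$b1 / (2 * f2$b2), v$peak_mass + 0.5, tolerance = 1e-6)

  # symmetric exact data about 0.82
  m <- seq(0.42, 1.22, length.out = 21)
  d <- data.frame(mass = m, response = 3 - 2 * (m - 0.82)^2,
                  rabbit_id = paste0("r", seq_along(m)))
  fs <- fit_quadratic(d, "peak")
  expect_equal(-fs$b1 / (2 * fs$b2), 0.82, tolerance = 1e-8)

  expect_error(vertex(fit_quadratic(
    data.frame(mass = m, response = 1 + m^2, rabbit_id = paste0("r", seq_along(m))),
    "peak")), "no-interior-maximum")
})

test_that("the profiled GLS engine agrees with nlme on its shared family", {
  set.seed(5)
  m <- runif(60, 0.2, 1.4)
  y <- 4 + 3 * m - 2 * m^2 + rnorm(60, 0, 0.3 * (0.2 + m))  # sd grows with mass
  d <- data.frame(mass = m, response = y, rabbit_id = paste0("r", 1:60))
  f <- fit_quadratic(d, "peak")
  g <- nlme::gls(response ~ mass + I(mass^2), data = f$data,
                 weights = nlme::varConstPower(form = ~mass,
                                               fixed = list(power = 1)),
                 method = "ML")
  expect_lt(max(abs(coef(g) - c(f$b0, f$b1, f$b2))), 0.02)
  # the profile optimum is never worse than nlme's
  expect_gte(f$model$logLik, as.numeric(logLik(g)) - 1e-3)
})

test_that("repeatability behaves at its limits and is invariant", {
  d_perfect <- data.frame(rabbit_id = rep(letters[1:10], each = 4),
                          value = rep(rnorm(10), each = 4))
  expect_gt(repeatability_icc(d_perfect, n_boot = 0)$icc, 0.999)

  set.seed(6)
  d_null <- data.frame(rabbit_id = sample(rep(letters[1:10], each = 10)),
                       value = rnorm(100))
  expect_lt(repeatability_icc(d_null, n_boot = 0)$icc, 0.15)

  dat <- cohort_quad_data(seed = 35)
  d <- data.frame(rabbit_id = dat$a$rabbit_id, value = dat$a$response)
  base <- repeatability_icc(d, n_boot = 0)$icc
  perm <- do.call(rbind, lapply(split(d, d$rabbit_id),
                                function(x) x[sample(nrow(x)), ]))
  expect_equal(repeatability_icc(perm, n_boot = 0)$icc, base, tolerance = 1e-6)
  d_shift <- transform(d, value = value + 100)
  expect_equal(repeatability_icc(d_shift, n_boot = 0)$icc, base,
               tolerance = 1e-6)
  expect_error(repeatability_icc(data.frame(rabbit_id = letters[1:5],
                                            value = rnorm(5)), n_boot = 0),
               "insufficient-replication")
  ci <- repeatability_icc(d, n_boot = 50, seed = 7)
  expect_true(ci$ci[1] <= ci$icc && ci$icc <= ci$ci[2])
})

test_that("group comparisons report Welch t and categorized Cohen's d", {
  x <- c(1, 2, 3, 4)
  cmp <- compare_groups(x, x)
  expect_equal(cmp$d, 0)
  expect_equal(cmp$category, "very small")

  set.seed(8)
  a <- rnorm(2000); b <- rnorm(2000) - 1
  cmp2 <- compare_groups(a, b)
  expect_lt(abs(cmp2$d - 1), 0.1)
  expect_lt(cmp2$p, 1e-10)

  expect_equal(effect_category(1.27), "very large")
  expect_equal(effect_category(0.25), "small")
  expect_equal(effect_category(0.65), "moderate")
  expect_equal(effect_category(2.5), "huge")
  expect_error(compare_groups(c(1, 1), c(1, 1)), "undefined-d")
})

test_that("Box-Cox standardization finds the generating transform", {
  set.seed(9)
  x <- rnorm(300, 10, 1)
  bc <- boxcox_z(x)
  expect_lt(abs(bc$lambda - 1), 0.5)
  expect_lt(abs(mean(bc$z)), 1e-9)
  expect_lt(abs(sd(bc$z) - 1), 1e-9)

  ln <- exp(rnorm(300))
  expect_lt(abs(boxcox_z(ln)$lambda), 0.2)
  expect_error(boxcox_z(rep(2, 10)), "degenerate-variance")
  expect_error(boxcox_z(c(-1, 2, 3, 4)), "domain error")
})

test_that("the one-tailed Pearson test matches theory and inverts", {
  x <- 1:10
  p1 <- one_tailed_pearson(x, 2 * x + 1)
  expect_equal(p1$r, 1)
  expect_lt(p1$p, 1e-12)

  # p-values uniform under the null
  set.seed(10)
  ps <- vapply(1:300, function(i) one_tailed_pearson(rnorm(15), rnorm(15))$p, 0)
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_gt(min(ps), 0); expect_lt(max(ps), 1)

  # inversion round trip at the juvenile survival test's printed p and n
  r <- pearson_r_from_p(0.115, 15)
  expect_lt(abs(r - 0.33), 0.01)
  # data constructed with exactly this sample correlation reproduce the p
  set.seed(11)
  x2 <- as.numeric(scale(rnorm(15)))
  e <- as.numeric(scale(resid(lm(rnorm(15) ~ x2))))
  y2 <- r * x2 + sqrt(1 - r^2) * e
  expect_equal(one_tailed_pearson(x2, y2)$p, 0.115, tolerance = 1e-6)
  expect_error(one_tailed_pearson(rep(1, 10), rnorm(10)), "undefined-r")
})

test_that("Fisher-z power analysis is self-consistent", {
  for (r in c(0.2, 0.33, 0.5)) {
    n <- required_n(r, 0.8)
    expect_gte(correlation_power(r, n), 0.8)
    expect_lt(correlation_power(r, n - 1), 0.8)
  }
  expect_gt(correlation_power(0.9, 15), correlation_power(0.3, 15))
  expect_error(required_n(0, 0.8), "unreachable-n")
  expect_error(correlation_power(1, 10), "domain error")
})
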