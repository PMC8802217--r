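# a known recursive structure used across these tests
sim_path_data <- function(n, seed, null_edge = FALSE) {
  set.seed(seed)
  mb <- rnorm(n)
  pmusc <- 0.9 * mb + sqrt(1 - 0.81) * rnorm(n)
  pcom <- 0.5 * mb + 0.3 * pmusc + 0.6 * rnorm(n)
  acom <- 0.7 * pcom - 0.4 * mb + 0.5 * rnorm(n)
  d <- data.frame(mb = mb, pmusc = pmusc, pcom = pcom, acom = acom)
  if (null_edge) d$stroke <- rnorm(n)   # unrelated to everything
  standardize(d)
}

test_that("standardization contracts hold", {
  d <- data.frame(a = rnorm(20, 5, 3), b = runif(20))
  z <- standardize(d)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(vapply(z, sd, 0) - 1)), 1e-12)
  # affine invariance
  z2 <- standardize(transform(d, a = 10 * a - 4))
  expect_equal(z2$a, z$a, tolerance = 1e-12)
  # two rows give +/- 1/sqrt(2) under the n - 1 convention
  z3 <- standardize(data.frame(a = c(0, 1)))
  expect_equal(sort(z3$a), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_error(standardize(data.frame(a = rep(1, 5))), "degenerate-variance")
})

test_that("path specs enforce recursivity", {
  expect_error(path_spec(c("a -> b", "b -> c", "c -> a")), "recursive")
  sp <- path_spec(c("mb -> pcom", "pmusc -> pcom", "pcom -> acom",
                    "mb -> acom"))
  expect_setequal(sp$exogenous, c("mb", "pmusc"))
  expect_setequal(sp$endogenous, c("pcom", "acom"))
})

test_that("the saturated model reproduces the sample matrix identically", {
  d <- sim_path_data(400, 21)
  sp <- path_spec(c("mb -> pmusc", "mb -> pcom", "pmusc -> pcom",
                    "mb -> acom", "pmusc -> acom", "pcom -> acom"))
  fit <- fit_path(sp, d)
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 1e-6)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
  expect_lt(max(abs(fit$implied - cor(d))), 1e-8)
})

test_that("ML estimates equal per-equation least squares on recursive models", {
  d <- sim_path_data(800, 22)
  sp <- path_spec(c("mb -> pcom", "pmusc -> pcom", "pcom -> acom",
                    "mb -> acom"))
  fit <- fit_path(sp, d)
  for (v in names(fit$ols)) {
    ols <- fit$ols[[v]]$beta
    sel <- fit$edges$to == v
    est <- fit$edges$beta[sel][match(names(ols), fit$edges$from[sel])]
    expect_lt(max(abs(est - ols)), 1e-6)
  }
})

test_that("a large-sample fit recovers the generating coefficients", {
  d <- sim_path_data(5000, 23)
  sp <- path_spec(c("mb -> pcom", "pmusc -> pcom", "pcom -> acom",
                    "mb -> acom"))
  fit <- fit_path(sp, d)
  get <- function(f, t) fit$edges$beta[fit$edges$from == f & fit$edges$to == t]
  # direct check against per-equation OLS on the same sample
  ols <- lm(acom ~ pcom + mb, data = d)
  expect_lt(abs(get("pcom", "acom") - coef(ols)["pcom"]), 1e-4)
  expect_lt(abs(get("mb", "acom") - coef(ols)["mb"]), 1e-4)
  # population-level recovery within 0.03 (coefficients on the z scale)
  pop <- lm(acom ~ pcom + mb,
            data = standardize(sim_path_data(200000, 99)))
  expect_lt(abs(get("pcom", "acom") - coef(pop)["pcom"]), 0.03)
  expect_lt(abs(get("mb", "acom") - coef(pop)["mb"]), 0.03)
  expect_true(all(fit$r2 > 0 & fit$r2 < 1))
})

test_that("pruning removes exactly the injected null edge", {
  # the null edge sits at the nominal alpha level, so judge over three seeds
  sp <- path_spec(c("mb -> pcom", "pmusc -> pcom", "pcom -> acom",
                    "mb -> acom", "stroke -> acom"))
  prunes <- lapply(c(101, 102, 103), function(sd) {
    prune(sp, sim_path_data(5000, sd, null_edge = TRUE))
  })
  removed_stroke <- vapply(prunes, function(pr) {
    nrow(pr$removed) == 1 && pr$removed$from == "stroke"
  }, TRUE)
  expect_gte(sum(removed_stroke), 2)
  pr <- prunes[[which(removed_stroke)[1]]]
  expect_true(all(pr$fit$edges$p <= 0.05))
  # a fully significant model is a fixed point
  d <- sim_path_data(5000, c(101, 102, 103)[which(removed_stroke)[1]],
                     null_edge = TRUE)
  pr2 <- prune(pr$spec, d)
  expect_equal(nrow(pr2$removed), 0)
  expect_equal(pr2$spec$edges, pr$spec$edges)
})

test_that("chi-square grows monotonically as edges are removed", {
  d <- sim_path_data(1000, 25)
  full <- c("mb -> pcom", "pmusc -> pcom", "pcom -> acom", "mb -> acom")
  chis <- vapply(seq_along(full), function(k) {
    fit_path(path_spec(full[seq_len(k)],
                       vars = c("mb", "pmusc", "pcom", "acom")), d)$chisq
  }, 0)
  expect_true(all(diff(rev(chis)) >= -1e-8))
  fits <- lapply(seq_along(full), function(k)
    fit_path(path_spec(full[seq_len(k)], vars = c("mb", "pmusc", "pcom", "acom")), d))
  for (f in fits) {
    expect_gte(f$cfi, 0); expect_lte(f$cfi, 1); expect_gte(f$rmsea, 0)
  }
})

test_that("total effects decompose into direct plus indirect paths", {
  d <- sim_path_data(2000, 26)
  sp <- path_spec(c("mb -> pcom", "pmusc -> pcom", "pcom -> acom",
                    "mb -> acom"))
  fit <- fit_path(sp, d)
  get <- function(f, t) fit$edges$beta[fit$edges$from == f & fit$edges$to == t]
  expect_equal(total_effect(fit, "mb", "acom"),
               get("mb", "acom") + get("mb", "pcom") * get("pcom", "acom"),
               tolerance = 1e-12)
})
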