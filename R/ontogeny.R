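#' @title Ontogenetic performance models and cohort statistics
#'
#' @description
#' Statistical layer for the ontogenetic analysis: quadratic performance-mass
#' models (mixed-effects per trial, GLS on per-individual peaks) with error sd
#' modelled as a linear function of mass, AICc model comparison against the
#' linear alternative, vertex (peak-performance mass) estimation with
#' case-resampling bootstrap confidence intervals, log-log allometry with
#' similarity verdicts, repeatability (ICC) with parametric bootstrap, Welch
#' comparisons with Cohen's d, Box-Cox standardization, one-tailed Pearson
#' correlation and Fisher-z power analysis.
#'
#' @name burstloco-ontogeny
NULL

# AICc with small-sample correction
aicc <- function(model, n) {
  if (is.list(model) && !is.null(model$logLik) && !is.null(model$df)) {
    ll <- model$logLik; k <- model$df
  } else {
    llo <- stats::logLik(model)
    ll <- as.numeric(llo); k <- attr(llo, "df")
  }
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# heteroscedastic structure: residual sd proportional to (c + mass),
# i.e. linear in the predictor
.var_lin <- function() nlme::varConstPower(form = ~mass, fixed = list(power = 1))

# GLS with residual sd = s * (1 + c * mass), fit by profiled maximum
# likelihood: for fixed c the problem is weighted least squares, so the
# scalar profile over c is optimized directly. Equivalent to gls() with a
# constant-plus-power variance function (power fixed at 1), but fast enough
# to sit inside the case bootstrap.
.gls_sdlin <- function(d, quadratic = TRUE) {
  X <- if (quadratic) cbind(1, d$mass, d$mass^2) else cbind(1, d$mass)
  y <- d$response
  m <- d$mass
  n <- length(y)
  prof <- function(cc) {
    sdf <- 1 + cc * m
    if (any(sdf <= 1e-8)) return(-1e10)
    w <- 1 / sdf^2
    fit <- stats::lm.wfit(X, y, w)
    s2 <- sum(w * fit$residuals^2) / n
    if (s2 <= 0) return(-1e10)
    -n / 2 * log(s2) - sum(log(sdf)) - n / 2 * (1 + log(2 * pi))
  }
  lo <- -0.99 / max(m)
  opt <- stats::optimize(prof, c(lo, 100), maximum = TRUE, tol = 1e-8)
  cc <- opt$maximum
  w <- 1 / (1 + cc * m)^2
  fit <- stats::lm.wfit(X, y, w)
  s2 <- sum(w * fit$residuals^2) / n
  list(coefficients = unname(fit$coefficients), fitted = as.numeric(X %*% fit$coefficients),
       logLik = opt$objective, df = ncol(X) + 2, c = cc, sigma = sqrt(s2))
}

#' Fit quadratic (and linear) performance-mass models
#'
#' At `level = "trial"` the response is modelled per trial with a random
#' intercept per individual (maximum likelihood, so AICc comparison is valid)
#' and residual sd linear in mass; at `level = "peak"` each individual
#' contributes its maximum and the model is generalized least squares with the
#' same variance function. Exact (noise-free) data are detected and fall back
#' to ordinary least squares, since a degenerate residual variance breaks the
#' GLS machinery.
#'
#' @param data data frame with columns `mass`, `response`, `rabbit_id`.
#' @param level `"peak"` or `"trial"`.
#' @param compare also fit the linear alternative for AICc comparison
#'   (default TRUE; bootstrap refits skip it).
#' @return A `quadratic_fit`: list with coefficients `b0, b1, b2`, the fitted
#'   models (`model`, `model_linear`), `aicc` (named vector, quadratic and
#'   linear), `r2` (marginal R^2 at trial level, R^2 at peak level), `level`,
#'   and the model-ready data.
#' @export
fit_quadratic <- function(data, level = c("peak", "trial"), compare = TRUE) {
  level <- match.arg(level)
  stopifnot(all(c("mass", "response", "rabbit_id") %in% names(data)))
  if (length(unique(data$mass)) < 3L) {
    stop("validation error: need at least 3 distinct masses")
  }

  if (level == "peak") {
    d <- do.call(rbind, lapply(split(data, data$rabbit_id), function(x) {
      x[which.max(x$response), c("rabbit_id", "mass", "response")]
    }))
    n <- nrow(d)
    ols_q <- stats::lm(response ~ mass + I(mass^2), data = d)
    exact <- stats::sigma(ols_q) < 1e-8 * max(1, stats::sd(d$response))
    ml <- NULL
    if (exact) {
      mq <- ols_q
      if (compare) ml <- stats::lm(response ~ mass, data = d)
    } else {
      mq <- .gls_sdlin(d, quadratic = TRUE)
      if (compare) ml <- .gls_sdlin(d, quadratic = FALSE)
    }
    pred <- if (inherits(mq, "lm")) as.numeric(stats::fitted(mq)) else mq$fitted
    r2 <- 1 - sum((d$response - pred)^2) / sum((d$response - mean(d$response))^2)
  } else {
    d <- data[c("rabbit_id", "mass", "response")]
    n <- nrow(d)
    if (sum(table(d$rabbit_id) >= 2L) < 2L) {
      stop("validation error: per-trial level requires >= 2 rabbits with >= 2 trials")
    }
    mq <- nlme::lme(response ~ mass + I(mass^2), random = ~ 1 | rabbit_id,
                    data = d, weights = .var_lin(), method = "ML",
                    control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                               returnObject = TRUE))
    ml <- if (compare) nlme::lme(response ~ mass, random = ~ 1 | rabbit_id,
                    data = d, weights = .var_lin(), method = "ML",
                    control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                               returnObject = TRUE))
    # marginal R^2: variance of fixed-effect predictions over total
    b <- nlme::fixef(mq)
    pred <- b[1] + b[2] * d$mass + b[3] * d$mass^2
    vf <- stats::var(pred)
    vr <- as.numeric(nlme::VarCorr(mq)[1, 1])
    sd_i <- attr(mq$residuals, "std")
    ve <- mean(sd_i^2)
    r2 <- vf / (vf + vr + ve)
  }

  b <- if (inherits(mq, "lme")) nlme::fixef(mq) else
    if (inherits(mq, "lm")) stats::coef(mq) else mq$coefficients
  structure(list(level = level, model = mq, model_linear = ml,
                 b0 = unname(b[1]), b1 = unname(b[2]), b2 = unname(b[3]),
                 aicc = c(quadratic = aicc(mq, n),
                          linear = if (is.null(ml)) NA_real_ else aicc(ml, n)),
                 r2 = r2, n = n, data = d),
            class = "quadratic_fit")
}

#' @exportS3Method base::print
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit level=%s> y = %.4g %+.4g m %+.4g m^2 | AICc quad %.2f, linear %.2f | R2 %.3f\n",
              x$level, x$b0, x$b1, x$b2, x$aicc["quadratic"], x$aicc["linear"], x$r2))
  invisible(x)
}

#' Vertex (peak-performance mass) with bootstrap confidence intervals
#'
#' The vertex of the fitted parabola is `-b1 / (2 b2)`, requiring negative
#' curvature. Confidence intervals come from a case-resampling bootstrap with
#' the individual as resampling unit (all of an individual's trials travel
#' with it), percentile method. When a growth model is supplied the vertex
#' mass (and each bootstrap draw) is mapped to age in days.
#'
#' @param fit a [fit_quadratic()] result.
#' @param growth optional [fit_growth_model()] result for the age mapping.
#' @param n_boot bootstrap draws (default 2000).
#' @param seed integer seed for the resampling.
#' @param level confidence level.
#' @return A `vertex_estimate`: list with `peak_mass`, `mass_ci`, `peak_age`,
#'   `age_ci` (NA without a growth model), `n_boot_ok`.
#' @export
vertex <- function(fit, growth = NULL, n_boot = 2000, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "quadratic_fit"))
  if (!is.finite(fit$b2) || fit$b2 >= 0) {
    stop("no-interior-maximum error: quadratic coefficient must be negative")
  }
  peak <- -fit$b1 / (2 * fit$b2)
  ids <- unique(fit$data$rabbit_id)
  by_id <- split(fit$data, fit$data$rabbit_id)

  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      take <- sample(ids, length(ids), replace = TRUE)
      dd <- do.call(rbind, lapply(seq_along(take), function(j) {
        x <- by_id[[take[j]]]
        x$rabbit_id <- paste0(x$rabbit_id, "_", j)   # keep resampled ids distinct
        x
      }))
      f <- tryCatch(fit_quadratic(dd, level = fit$level, compare = FALSE),
                    error = function(e) NULL)
      if (is.null(f) || !is.finite(f$b2) || f$b2 >= 0) return(NA_real_)
      -f$b1 / (2 * f$b2)
    }, 0)
  })
  ok <- draws[is.finite(draws)]
  al <- (1 - level) / 2
  mass_ci <- stats::quantile(ok, c(al, 1 - al), names = FALSE)

  if (!is.null(growth)) {
    age <- suppressWarnings(predict_age(growth, peak))
    age_ci <- suppressWarnings(range(predict_age(growth, mass_ci)))
  } else {
    age <- NA_real_; age_ci <- c(NA_real_, NA_real_)
  }
  structure(list(peak_mass = peak, mass_ci = mass_ci, peak_age = age,
                 age_ci = age_ci, n_boot_ok = length(ok), level = level),
            class = "vertex_estimate")
}

#' @exportS3Method base::print
print.vertex_estimate <- function(x, ...) {
  cat(sprintf("<vertex_estimate> peak mass %.3f kg [%.3f, %.3f]", x$peak_mass,
              x$mass_ci[1], x$mass_ci[2]))
  if (is.finite(x$peak_age)) {
    cat(sprintf("; age %.1f d [%.1f, %.1f]", x$peak_age, x$age_ci[1], x$age_ci[2]))
  }
  cat(sprintf(" (%d bootstrap draws)\n", x$n_boot_ok))
  invisible(x)
}

#' Evaluate a fitted quadratic at given masses
#'
#' @param fit a [fit_quadratic()] result.
#' @param mass masses (kg); values outside the fitted range raise an
#'   extrapolation warning.
#' @return Predicted response.
#' @export
predict_accel <- function(fit, mass) {
  stopifnot(inherits(fit, "quadratic_fit"))
  rng <- range(fit$data$mass)
  if (any(mass < rng[1] - 1e-9 | mass > rng[2] + 1e-9)) {
    warning("extrapolating the quadratic fit beyond the fitted mass range")
  }
  fit$b0 + fit$b1 * mass + fit$b2 * mass^2
}

#' Log-log allometry of muscle power on body mass
#'
#' Ordinary least squares of log10(P_musc) on log10(M_b); the exponent CI
#' comes from the slope's standard error, and similarity verdicts state
#' whether the CI contains the geometric (1.00) and mechanical (1.33) null
#' exponents.
#'
#' @param p_musc per-individual power capacity (W), > 0.
#' @param mass body masses (kg), > 0.
#' @param level confidence level.
#' @return An `allometry_fit`: list with `coefficient` (the multiplier on the
#'   raw scale), `exponent`, `exponent_ci`, `r2`, `verdicts` (named logicals
#'   `contains_1.00`, `contains_1.33`), `ci_infinite` flag.
#' @export
fit_allometry <- function(p_musc, mass, level = 0.95) {
  if (length(p_musc) < 2L) stop("validation error: need at least 2 individuals")
  if (any(p_musc <= 0) || any(mass <= 0)) {
    stop("domain error: power and mass must be > 0")
  }
  fit <- stats::lm(lp ~ lm_, data = data.frame(lp = log10(p_musc), lm_ = log10(mass)))
  sm <- summary(fit)
  expo <- stats::coef(fit)[2]
  df <- fit$df.residual
  ci_inf <- df < 1L
  if (ci_inf) {
    ci <- c(-Inf, Inf)
  } else {
    se <- sm$coefficients[2, 2]
    tq <- stats::qt(1 - (1 - level) / 2, df)
    ci <- expo + c(-1, 1) * tq * se
  }
  structure(list(coefficient = unname(10^stats::coef(fit)[1]),
                 exponent = unname(expo), exponent_ci = unname(ci),
                 r2 = sm$r.squared,
                 verdicts = c(contains_1.00 = ci[1] <= 1.00 && 1.00 <= ci[2],
                              contains_1.33 = ci[1] <= 1.33 && 1.33 <= ci[2]),
                 ci_infinite = ci_inf, fit = fit),
            class = "allometry_fit")
}

#' @exportS3Method base::print
print.allometry_fit <- function(x, ...) {
  cat(sprintf("<allometry_fit> P = %.3g * M^%.3f [%.3f, %.3f], R2 = %.3f\n",
              x$coefficient, x$exponent, x$exponent_ci[1], x$exponent_ci[2], x$r2))
  invisible(x)
}

#' Repeatability (intraclass correlation) of a performance trait
#'
#' ICC = between-individual variance / total variance from a random-intercept
#' model; the CI comes from a parametric bootstrap (simulate from the fitted
#' model, refit, percentile interval).
#'
#' @param data data frame with columns `rabbit_id` and `value`.
#' @param n_boot parametric bootstrap draws.
#' @param seed integer seed.
#' @param level confidence level.
#' @return List with `icc`, `ci`, `var_between`, `var_within`.
#' @export
repeatability_icc <- function(data, n_boot = 1000, seed = 1L, level = 0.95) {
  stopifnot(all(c("rabbit_id", "value") %in% names(data)))
  tab <- table(data$rabbit_id)
  if (sum(tab >= 2L) < 2L) {
    stop("insufficient-replication error: need >= 2 rabbits with >= 2 trials")
  }
  d <- data.frame(rabbit_id = factor(data$rabbit_id), value = data$value)
  m <- lme4::lmer(value ~ 1 + (1 | rabbit_id), data = d, REML = TRUE)
  icc_of <- function(mod) {
    vc <- as.data.frame(lme4::VarCorr(mod))
    vb <- vc$vcov[vc$grp == "rabbit_id"]
    vw <- vc$vcov[vc$grp == "Residual"]
    vb / (vb + vw)
  }
  icc <- icc_of(m)
  ci <- if (n_boot > 0) {
    draws <- with_seed(seed, {
      sims <- stats::simulate(m, nsim = n_boot)
      vapply(sims, function(y) {
        mm <- tryCatch(suppressMessages(lme4::refit(m, newresp = y)),
                       error = function(e) NULL)
        if (is.null(mm)) NA_real_ else icc_of(mm)
      }, 0)
    })
    al <- (1 - level) / 2
    stats::quantile(draws[is.finite(draws)], c(al, 1 - al), names = FALSE)
  } else c(NA_real_, NA_real_)
  vc <- as.data.frame(lme4::VarCorr(m))
  list(icc = icc, ci = ci,
       var_between = vc$vcov[vc$grp == "rabbit_id"],
       var_within = vc$vcov[vc$grp == "Residual"])
}

#' Cohen's d effect-size category
#'
#' Thresholds (on |d|): 0.2 small, 0.5 moderate, 0.8 large, 1.2 very large,
#' 2.0 huge; anything below 0.2 is very small.
#'
#' @param d Cohen's d.
#' @return Character category.
#' @export
effect_category <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, 1.2, 2.0, Inf),
      labels = c("very small", "small", "moderate", "large", "very large", "huge"),
      right = FALSE) |> as.character()
}

#' Welch comparison of two groups with Cohen's d
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, `d`, `category`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("validation error: each group needs n >= 2")
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("undefined-d error: zero variance in both groups")
  tt <- stats::t.test(a, b)
  sp <- sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
               (length(a) + length(b) - 2))
  d <- (mean(a) - mean(b)) / sp
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = d, category = effect_category(d))
}

#' Box-Cox transform and standardize to z-scores
#'
#' Lambda is chosen by profile maximum likelihood on a fixed grid (-2 to 2,
#' step 0.01); the transformed values are standardized to mean 0, sd 1.
#'
#' @param values positive reals.
#' @return List with `z` (standardized transformed values) and `lambda`.
#' @export
boxcox_z <- function(values) {
  if (any(values <= 0)) stop("domain error: Box-Cox requires positive values")
  if (stats::sd(values) == 0) stop("degenerate-variance error: constant input")
  n <- length(values)
  lx <- sum(log(values))
  grid <- seq(-2, 2, by = 0.01)
  ll <- vapply(grid, function(lam) {
    y <- if (abs(lam) < 1e-12) log(values) else (values^lam - 1) / lam
    v <- stats::var(y) * (n - 1) / n
    -n / 2 * log(v) + (lam - 1) * lx
  }, 0)
  lam <- grid[which.max(ll)]
  y <- if (abs(lam) < 1e-12) log(values) else (values^lam - 1) / lam
  list(z = as.numeric(scale(y)), lambda = lam)
}

#' One-tailed Pearson correlation (positive association)
#'
#' `t = r sqrt((n-2)/(1-r^2))`, `p = P(T >= t)` on `n - 2` df.
#'
#' @param x,y numeric vectors, n >= 4.
#' @return List with `r`, `t`, `df`, `p`.
#' @export
one_tailed_pearson <- function(x, y) {
  n <- length(x)
  if (n < 4L || length(y) != n) stop("validation error: need paired n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-r error: zero variance")
  }
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, df = n - 2, p = stats::pt(t, n - 2, lower.tail = FALSE))
}

#' Invert a one-tailed Pearson p-value to the correlation
#'
#' @param p one-tailed p-value.
#' @param n sample size (>= 4).
#' @return The correlation r with `one_tailed_pearson` p equal to `p` at this
#'   n.
#' @export
pearson_r_from_p <- function(p, n) {
  if (n < 4L) stop("validation error: need n >= 4")
  t <- stats::qt(1 - p, n - 2)
  t / sqrt(t^2 + n - 2)
}

#' Power of a one-tailed correlation test (Fisher-z approximation)
#'
#' `power = Phi(atanh(r) sqrt(n-3) - z_(1-alpha))`.
#'
#' @param r correlation, |r| < 1.
#' @param n sample size (>= 4).
#' @param alpha one-tailed significance level.
#' @return Power in (0, 1).
#' @export
correlation_power <- function(r, n, alpha = 0.05) {
  if (abs(r) >= 1) stop("domain error: |r| must be < 1")
  if (n < 4) stop("validation error: need n >= 4")
  stats::pnorm(atanh(r) * sqrt(n - 3) - stats::qnorm(1 - alpha))
}

#' Sample size required for a target power (Fisher-z)
#'
#' Inverts [correlation_power()] for n, ceiling to an integer.
#'
#' @param r correlation, 0 < |r| < 1 (r = 0 with a power target above alpha is
#'   unreachable).
#' @param power_target target power.
#' @param alpha one-tailed significance level.
#' @return Required total sample size n.
#' @export
required_n <- function(r, power_target = 0.8, alpha = 0.05) {
  if (abs(r) >= 1) stop("domain error: |r| must be < 1")
  if (r == 0 && power_target > alpha) {
    stop("unreachable-n error: r = 0 cannot attain power above alpha")
  }
  zr <- atanh(abs(r))
  n <- ((stats::qnorm(power_target) + stats::qnorm(1 - alpha)) / zr)^2 + 3
  as.integer(ceiling(n))
}
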