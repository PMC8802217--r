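#' @title Marker smoothing and kinematic velocity
#'
#' @description
#' Hip-marker trajectories are digitized at 250 Hz and carry digitizing noise
#' and occasional invisible frames. Each axis is fit with a quintic (degree-5)
#' penalized B-spline whose smoothing parameter is chosen by bisection as the
#' largest smoothing for which the residual criterion still holds; the fitted
#' spline interpolates positions at invisible frames and supplies an analytic
#' first derivative for the kinematic velocity profile and the seed estimate of
#' initial velocity.
#'
#' @name burstloco-kinematics
NULL

# quintic P-spline for one axis: uniform knots one per frame, 4th-order
# difference penalty (null space spans cubic trajectories, i.e. smoothly
# accelerating motion), ridge-free closed-form solve per lambda
.pspline_fit <- function(t, y, lambda, range = base::range(t)) {
  h <- stats::median(diff(t))
  knots <- seq(range[1] - 5.5 * h, range[2] + 5.5 * h, by = h)
  B <- splines::splineDesign(knots, t, ord = 6L)
  k <- ncol(B)
  D <- diff(diag(k), differences = 4L)
  BtB <- crossprod(B)
  P <- crossprod(D)
  A <- BtB + lambda * P
  rhs <- crossprod(B, y)
  coef <- solve(A, rhs)
  coef <- coef + solve(A, rhs - A %*% coef)   # iterative refinement

  list(knots = knots, coef = as.numeric(coef), fitted = as.numeric(B %*% coef))
}

.pspline_eval <- function(fit, t, deriv = 0L) {
  B <- splines::splineDesign(fit$knots, t, ord = 6L,
                             derivs = rep(deriv, length(t)))
  as.numeric(B %*% fit$coef)
}

#' Smooth a marker trajectory with a quintic penalized spline
#'
#' Fit is per axis, to visible frames only. The smoothing parameter is the
#' largest value for which the residual criterion holds, found by bisection on
#' log(lambda): with `tolerance_mode = "per_frame"` (default) the criterion is
#' mean squared residual over visible frames <= `tolerance`; with `"total"` it
#' is the summed squared residual <= `tolerance`. Positions at invisible
#' frames are interpolated from the fitted spline.
#'
#' @param markers a [marker_trajectory()].
#' @param tolerance residual tolerance in mm^2 (default 0.75).
#' @param tolerance_mode `"per_frame"` (mean squared residual per visible
#'   frame) or `"total"` (summed squared residual).
#' @return A `smoothed_trajectory`: list with `time`, `position` (n x 3,
#'   metres, fore-aft/mediolateral/vertical), `velocity` (n x 3, m/s), the
#'   per-axis spline fits, and the smoothing parameters used.
#' @export
smooth_trajectory <- function(markers, tolerance = 0.75,
                              tolerance_mode = c("per_frame", "total")) {
  stopifnot(inherits(markers, "marker_trajectory"))
  tolerance_mode <- match.arg(tolerance_mode)
  if (tolerance <= 0) stop("validation error: tolerance must be > 0")
  vis <- markers$visible
  if (sum(vis) < 7L) stop("insufficient-data error: need at least 7 visible frames")
  tol_m2 <- tolerance * 1e-6           # mm^2 -> m^2
  tv <- markers$time[vis]
  n_vis <- sum(vis)

  rng <- range(markers$time)
  fit_axis <- function(y) {
    yv <- y[vis]
    crit <- function(fit) {
      ssr <- sum((fit$fitted - yv)^2)
      if (tolerance_mode == "per_frame") ssr / n_vis else ssr
    }
    lo <- -12; hi <- 3                 # log10(lambda) bracket
    f_hi <- .pspline_fit(tv, yv, 10^hi, rng)
    if (crit(f_hi) <= tol_m2) return(c(f_hi, lambda = 10^hi))
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      f <- .pspline_fit(tv, yv, 10^mid, rng)
      if (crit(f) <= tol_m2) lo <- mid else hi <- mid
    }
    c(.pspline_fit(tv, yv, 10^lo, rng), lambda = 10^lo)
  }

  fits <- list(x = fit_axis(markers$x), y = fit_axis(markers$y),
               z = fit_axis(markers$z))
  tt <- markers$time
  pos <- sapply(fits, .pspline_eval, t = tt, deriv = 0L)
  vel <- sapply(fits, .pspline_eval, t = tt, deriv = 1L)
  structure(list(time = tt, position = pos, velocity = vel, fits = fits,
                 lambda = sapply(fits, `[[`, "lambda"),
                 rate = attr(markers, "rate"), visible = vis),
            class = "smoothed_trajectory")
}

#' Evaluate a smoothed trajectory at arbitrary times
#'
#' @param object a `smoothed_trajectory`.
#' @param t times (s) within the fitted range.
#' @param deriv 0 for position, 1 for velocity.
#' @param ... unused.
#' @return Matrix with columns x, y, z.
#' @export
predict.smoothed_trajectory <- function(object, t, deriv = 0L, ...) {
  if (min(t) < min(object$time) - 1e-9 || max(t) > max(object$time) + 1e-9) {
    stop("range error: evaluation times exceed the trajectory")
  }
  t <- pmin(pmax(t, min(object$time)), max(object$time))
  out <- vapply(object$fits, .pspline_eval, numeric(length(t)), t = t, deriv = deriv)
  matrix(out, nrow = length(t), dimnames = list(NULL, names(object$fits)))
}

#' Sagittal-plane kinematic velocity profile and seed initial velocity
#'
#' Differentiates the smoothed sagittal-plane (fore-aft x vertical)
#' displacement of the hip marker over a window spanning `frames_before`
#' frames before the contact period to `frames_after` frames after it. The
#' seed initial velocity is the mean fore-aft velocity over the pre-contact
#' frames.
#'
#' @param traj a `smoothed_trajectory` (see [smooth_trajectory()]).
#' @param contact_start stride/contact onset (s).
#' @param contact_end contact offset (s); defaults to `contact_start` when the
#'   window around onset alone is wanted.
#' @param frames_before,frames_after window extent in marker frames (default
#'   10 each, i.e. 40 ms at 250 Hz).
#' @return List with `profile` (data frame: `time`, `v_fa`, `v_v`, `speed` =
#'   sagittal-plane speed) and `v0_seed` (m/s).
#' @export
kinematic_velocity_window <- function(traj, contact_start, contact_end = NULL,
                                      frames_before = 10L, frames_after = 10L) {
  stopifnot(inherits(traj, "smoothed_trajectory"))
  if (is.null(contact_end)) contact_end <- contact_start
  dt <- 1 / traj$rate
  w0 <- contact_start - frames_before * dt
  w1 <- contact_end + frames_after * dt
  if (w0 < min(traj$time) - 1e-9 || w1 > max(traj$time) + 1e-9) {
    stop("range error: window exceeds the trajectory")
  }
  sel <- traj$time >= w0 - 1e-9 & traj$time <= w1 + 1e-9
  v_fa <- traj$velocity[sel, "x"]
  v_v <- traj$velocity[sel, "z"]
  profile <- data.frame(time = traj$time[sel], v_fa = v_fa, v_v = v_v,
                        speed = sqrt(v_fa^2 + v_v^2))
  pre <- profile$time < contact_start - 1e-9
  if (!any(pre)) stop("range error: no pre-contact frames in window")
  list(profile = profile, v0_seed = mean(profile$v_fa[pre]))
}
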