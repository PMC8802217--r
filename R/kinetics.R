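#' @title Stride segmentation and per-trial performance metrics
#'
#' @description
#' From a synchronized force trace and smoothed marker trajectory this module
#' derives the per-trial performance metrics of burst locomotion:
#' \itemize{
#'   \item mean COM acceleration `a_COM` = mean fore-aft force over the stride
#'     divided by body mass;
#'   \item escape speed `v_esc` = fore-aft impulse over mass plus initial
#'     velocity (trapezoidal quadrature at the force sampling rate);
#'   \item initial velocity `v0`, seeded kinematically and refined by matching
#'     kinetic and kinematic velocity profiles (least squares, closed form,
#'     with an iterative bounded search as cross-check);
#'   \item average COM mechanical power `P_COM` from positive fluctuations of
#'     COM kinetic + potential energy, divided by the hindlimb stroke
#'     duration;
#'   \item girdle-specific mean accelerations from the fore/hind plate split.
#' }
#'
#' @name burstloco-kinetics
NULL

GRAVITY <- 9.81

# trapezoidal integral of y over t restricted to a closed sample window
.trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

# sum channels across plates sharing one time base
total_force <- function(force) {
  pl <- split_plates(force)
  out <- pl[[1]][c("time", "f_fa", "f_v")]
  if (length(pl) > 1L) {
    for (p in pl[-1]) {
      if (nrow(p) != nrow(out) || max(abs(p$time - out$time)) > 1e-9) {
        stop("data error: plates do not share a common time base")
      }
      out$f_fa <- out$f_fa + p$f_fa
      out$f_v <- out$f_v + p$f_v
    }
  }
  out
}

#' Segment a stride from a force trace
#'
#' Stance on each plate is the set of contiguous intervals where vertical
#' force exceeds a threshold (default 2% of body weight, with a floor of 3x
#' the baseline noise level estimated from the first 40 ms of the trace);
#' intervals shorter than `min_stance` are dropped and gaps shorter than
#' `merge_gap` are bridged. The stride spans the first stance onset to the
#' last stance offset across plates. With two contacted plates the
#' earlier-contacting plate is assigned to the forelimb girdle and the later
#' to the hindlimb; with a single contacted plate the contact is taken as
#' hindlimb (half-bound propulsion is hindlimb dominated). Hindlimb stroke
#' duration is the hindlimb stance duration.
#'
#' @param force a [force_trace()].
#' @param body_mass body mass (kg), used for the default threshold.
#' @param threshold stance threshold (N); default `0.02 * body_mass * g`.
#' @param min_stance,merge_gap duration filters (s).
#' @return A `stride_segment`: list with `t0`, `t_end`, `stances` (data frame
#'   `plate, girdle, on, off`), `stroke` (s), `fore_plate`, `hind_plate`.
#' @export
segment_stride <- function(force, body_mass = NULL, threshold = NULL,
                           min_stance = 0.010, merge_gap = 0.010) {
  stopifnot(inherits(force, "force_trace"))
  if (is.null(threshold)) {
    if (is.null(body_mass)) {
      stop("validation error: give either threshold or body_mass")
    }
    threshold <- 0.02 * body_mass * GRAVITY
  }
  if (threshold <= 0) stop("validation error: threshold must be > 0")

  plates <- split_plates(force)
  intervals <- list()
  for (nm in names(plates)) {
    p <- plates[[nm]]
    dt <- 1 / attr(force, "rate")
    # detection on a 5-sample moving average, with a noise floor estimated
    # from the (unloaded) first 40 ms of the trace
    fv_s <- stats::filter(p$f_v, rep(1 / 5, 5), sides = 2)
    fv_s[is.na(fv_s)] <- p$f_v[is.na(fv_s)]
    base <- p$f_v[p$time <= min(p$time) + 0.040]
    thr <- max(threshold, 4 * stats::mad(base))
    above <- as.numeric(fv_s) > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    iv <- data.frame(on = p$time[starts[r$values]], off = p$time[ends[r$values]])
    # drop sub-threshold-duration blips, then bridge short gaps
    iv <- iv[iv$off - iv$on >= min_stance - dt / 2, , drop = FALSE]
    if (nrow(iv) > 1L) {
      keep <- iv[1, , drop = FALSE]
      for (i in 2:nrow(iv)) {
        if (iv$on[i] - keep$off[nrow(keep)] <= merge_gap + dt / 2) {
          keep$off[nrow(keep)] <- iv$off[i]
        } else keep <- rbind(keep, iv[i, ])
      }
      iv <- keep
    }
    if (nrow(iv)) {
      # snap smoothed-trace edges to the raw threshold crossings nearby
      for (i in seq_len(nrow(iv))) {
        near <- which(p$time >= iv$on[i] - 5 * dt & p$time <= iv$on[i] + 5 * dt &
                        p$f_v > thr)
        if (length(near)) iv$on[i] <- p$time[min(near)]
        near <- which(p$time >= iv$off[i] - 5 * dt & p$time <= iv$off[i] + 5 * dt &
                        p$f_v > thr)
        if (length(near)) iv$off[i] <- p$time[max(near)]
      }
      intervals[[nm]] <- cbind(plate = nm, iv)
    }
  }
  if (!length(intervals)) stop("no-stride error: no interval above threshold")

  onset <- vapply(intervals, function(d) min(d$on), 0)
  ord <- names(sort(onset))
  girdle <- if (length(ord) == 1L) "hind" else c("fore", rep("hind", length(ord) - 1L))
  names(girdle) <- ord
  st <- do.call(rbind, intervals[ord])
  st$girdle <- girdle[st$plate]
  rownames(st) <- NULL

  hind <- st[st$girdle == "hind", , drop = FALSE]
  structure(list(t0 = min(st$on), t_end = max(st$off),
                 stances = st[c("plate", "girdle", "on", "off")],
                 stroke = sum(hind$off - hind$on),
                 fore_plate = if (any(st$girdle == "fore")) st$plate[st$girdle == "fore"][1] else NA,
                 hind_plate = hind$plate[1]),
            class = "stride_segment")
}

#' @exportS3Method base::print
print.stride_segment <- function(x, ...) {
  cat(sprintf("<stride_segment> t0 = %.3f s, t_end = %.3f s, hindlimb stroke = %.3f s\n",
              x$t0, x$t_end, x$stroke))
  print(x$stances)
  invisible(x)
}

.window <- function(tf, t0, t_end) {
  sel <- tf$time >= t0 - 1e-9 & tf$time <= t_end + 1e-9
  if (sum(sel) < 2L) stop("range error: empty integration window")
  tf[sel, ]
}

#' Mean COM acceleration over the stride
#'
#' `a_COM` is the quotient of mean fore-aft force (trapezoidal mean over
#' `[t0, t_end]`, plates summed) and body mass.
#'
#' @param stride a [segment_stride()] result.
#' @param force a [force_trace()].
#' @param body_mass body mass (kg), > 0.
#' @return Mean acceleration (m/s^2).
#' @export
mean_acceleration <- function(stride, force, body_mass) {
  if (body_mass <= 0) stop("validation error: body_mass must be > 0")
  w <- .window(total_force(force), stride$t0, stride$t_end)
  .trapz(w$time, w$f_fa) / (body_mass * (max(w$time) - min(w$time)))
}

#' Escape speed from the fore-aft impulse
#'
#' `v_esc = integral(F_FA, t0..t_end) / M_b + v0` by trapezoidal quadrature at
#' the force sampling rate.
#'
#' @inheritParams mean_acceleration
#' @param v0 initial fore-aft COM velocity (m/s).
#' @return Escape speed (m/s).
#' @export
escape_speed <- function(stride, force, body_mass, v0) {
  if (body_mass <= 0) stop("validation error: body_mass must be > 0")
  if (!is.finite(v0)) stop("validation error: v0 must be finite")
  w <- .window(total_force(force), stride$t0, stride$t_end)
  if (anyNA(w$f_fa)) stop("data error: NaN in integration window")
  .trapz(w$time, w$f_fa) / body_mass + v0
}

# kinetic velocity increment relative to v(t0) = 0, evaluated at arbitrary
# times by linear interpolation of the cumulative trapezoidal impulse
.kinetic_dv <- function(force, stride, body_mass, at) {
  w <- .window(total_force(force), stride$t0, stride$t_end)
  I <- cumtrapz(w$time, w$f_fa) / body_mass
  stats::approx(w$time, I, xout = at, rule = 2)$y
}

#' Optimize initial velocity by kinetic/kinematic profile matching
#'
#' The kinetic profile is `v(t; v0) = v0 + cumulative integral(F_FA)/M_b`. The
#' sum of squared differences against the kinematic fore-aft velocity at the
#' marker frames inside the stride window is quadratic in `v0`, so the
#' minimizer is the mean residual (closed form); a bounded golden-section
#' search mirrors the iterative procedure as a cross-check and a numerical
#' warning is raised if the two disagree beyond 1e-6 m/s.
#'
#' @inheritParams mean_acceleration
#' @param kin_profile result of [kinematic_velocity_window()] (or its
#'   `profile` data frame with columns `time`, `v_fa`).
#' @param v0_seed kinematic seed (m/s), centre of the search bracket.
#' @return List with `v0` (m/s), `ssd` ((m/s)^2), and `v0_iter` (the iterative
#'   cross-check).
#' @export
optimize_v0 <- function(stride, force, body_mass, kin_profile, v0_seed = 0) {
  prof <- if (is.data.frame(kin_profile)) kin_profile else kin_profile$profile
  sel <- prof$time >= stride$t0 - 1e-9 & prof$time <= stride$t_end + 1e-9
  if (sum(sel) < 2L) {
    stop("range error: kinematic profile does not overlap the stride window")
  }
  tt <- prof$time[sel]
  vk <- prof$v_fa[sel]
  dv <- .kinetic_dv(force, stride, body_mass, tt)
  resid <- vk - dv
  v0 <- mean(resid)
  ssd <- function(v) sum((v + dv - vk)^2)
  opt <- stats::optimize(ssd, interval = v0_seed + c(-2, 2), tol = 1e-9)
  if (abs(opt$minimum - v0) > 1e-6) {
    warning(sprintf("numerical warning: iterative v0 (%.8f) differs from closed form (%.8f)",
                    opt$minimum, v0))
  }
  list(v0 = v0, ssd = ssd(v0), v0_iter = opt$minimum)
}

#' Average COM mechanical power over the hindlimb stroke
#'
#' COM velocities are obtained by integrating `F_FA / M_b` (from `v0`) and
#' `(F_V - M_b g) / M_b` (from an assumed zero vertical velocity at stride
#' onset — trials start from a static start); COM height follows by
#' integrating vertical velocity. The instantaneous COM energy is
#' `E = 1/2 M (v_fa^2 + v_v^2) + M g h`; `P_COM` is the sum of positive
#' increments of E accumulated over `window` divided by the hindlimb stroke
#' duration.
#'
#' @inheritParams escape_speed
#' @param window `"stride"` (default): accumulate positive COM work over the
#'   whole stride; `"hindlimb_stance"`: over the hindlimb stance intervals
#'   only.
#' @param include_pe include the gravitational potential term (default TRUE);
#'   FALSE restricts E to kinetic energy.
#' @return Average COM power (W).
#' @export
com_power <- function(stride, force, body_mass, v0,
                      window = c("stride", "hindlimb_stance"),
                      include_pe = TRUE) {
  window <- match.arg(window)
  if (stride$stroke <= 0) stop("range error: hindlimb stroke duration is zero")
  w <- .window(total_force(force), stride$t0, stride$t_end)
  v_fa <- v0 + cumtrapz(w$time, w$f_fa) / body_mass
  v_v <- cumtrapz(w$time, (w$f_v - body_mass * GRAVITY) / body_mass)
  h <- cumtrapz(w$time, v_v)
  E <- 0.5 * body_mass * (v_fa^2 + v_v^2)
  if (include_pe) E <- E + body_mass * GRAVITY * h
  dE <- diff(E)
  if (window == "hindlimb_stance") {
    hs <- stride$stances[stride$stances$girdle == "hind", , drop = FALSE]
    mid <- (w$time[-1] + w$time[-nrow(w)]) / 2
    inside <- rowSums(outer(mid, hs$on, ">=") & outer(mid, hs$off, "<=")) > 0
    dE <- dE[inside]
  }
  sum(dE[dE > 0]) / stride$stroke
}

#' Acceleration from average power via the work-energy relation
#'
#' Under constant average power P applied over interval t, the COM velocity
#' grows as `v = sqrt(2 P t / M)`; differentiating gives the acceleration
#' `a = sqrt(P / (2 M t))`.
#'
#' @param p_com average COM power (W), > 0.
#' @param body_mass body mass (kg), > 0.
#' @param t hindlimb stroke duration (s), > 0.
#' @return Acceleration (m/s^2).
#' @export
work_energy_acceleration <- function(p_com, body_mass, t) {
  if (any(c(p_com, body_mass, t) <= 0)) {
    stop("domain error: all arguments must be > 0")
  }
  sqrt(p_com / (2 * body_mass * t))
}

#' Mean acceleration during forelimb versus hindlimb contact
#'
#' Per-girdle trapezoidal mean of that girdle's plate `F_FA / M_b` over its
#' stance intervals. A girdle with no stance is reported as NA (absent), not
#' an error.
#'
#' @inheritParams mean_acceleration
#' @return Named numeric: `fore_a`, `hind_a` (m/s^2).
#' @export
girdle_accelerations <- function(stride, force, body_mass) {
  plates <- split_plates(force)
  one <- function(g) {
    st <- stride$stances[stride$stances$girdle == g, , drop = FALSE]
    if (!nrow(st)) return(NA_real_)
    p <- plates[[as.character(st$plate[1])]]
    imp <- 0; dur <- 0
    for (i in seq_len(nrow(st))) {
      w <- .window(p, st$on[i], st$off[i])
      imp <- imp + .trapz(w$time, w$f_fa)
      dur <- dur + max(w$time) - min(w$time)
    }
    imp / (body_mass * dur)
  }
  c(fore_a = one("fore"), hind_a = one("hind"))
}

#' Process one trial end to end
#'
#' Runs the full chain: stride segmentation, marker smoothing, kinematic
#' velocity window, initial-velocity optimization, and all per-trial metrics.
#'
#' @param bundle a [trial_bundle()].
#' @param tolerance spline tolerance (mm^2), see [smooth_trajectory()].
#' @param threshold stance threshold override (N).
#' @param power_window passed to [com_power()] as `window`.
#' @return One-row data frame: `trial_id, rabbit_id, mass_kg, a_com, v0,
#'   v_esc, p_com, p_com_per_kg, stroke_s, fore_a, hind_a`.
#' @export
process_trial <- function(bundle, tolerance = 0.75, threshold = NULL,
                          power_window = "stride") {
  stopifnot(inherits(bundle, "trial_bundle"))
  M <- bundle$body_mass
  stride <- segment_stride(bundle$force, body_mass = M, threshold = threshold)
  traj <- smooth_trajectory(bundle$markers, tolerance = tolerance)
  kin <- kinematic_velocity_window(traj, stride$t0, stride$t_end)
  v0 <- optimize_v0(stride, bundle$force, M, kin, kin$v0_seed)$v0
  a <- mean_acceleration(stride, bundle$force, M)
  vesc <- escape_speed(stride, bundle$force, M, v0)
  p <- com_power(stride, bundle$force, M, v0, window = power_window)
  ga <- girdle_accelerations(stride, bundle$force, M)
  data.frame(trial_id = bundle$trial_id, rabbit_id = bundle$rabbit_id,
             mass_kg = M, a_com = a, v0 = v0, v_esc = vesc, p_com = p,
             p_com_per_kg = p / M, stroke_s = stride$stroke,
             fore_a = unname(ga["fore_a"]), hind_a = unname(ga["hind_a"]))
}

#' Process a list of trials into a performance table
#'
#' @param bundles list of [trial_bundle()]s.
#' @param ... passed to [process_trial()].
#' @return Data frame, one row per trial.
#' @export
process_trials <- function(bundles, ...) {
  do.call(rbind, lapply(bundles, process_trial, ...))
}
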