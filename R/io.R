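#' @title File formats, domain containers, and unit conventions
#'
#' @description
#' Containers used throughout the pipeline:
#' \describe{
#'   \item{force_trace}{synchronized force-plate time series for one trial;
#'     columns \code{time} (s), \code{plate} (id), \code{f_fa} (N, fore-aft,
#'     positive in the direction of travel) and \code{f_v} (N, vertical,
#'     positive up, unloaded baseline 0).}
#'   \item{marker_trajectory}{time-stamped 3-D hip-marker positions (m) with a
#'     per-frame visibility flag.}
#'   \item{trial_bundle}{one trial: ids, body mass (kg), force trace and marker
#'     trajectory sharing the common trigger at t = 0, collar status.}
#' }
#' All internal units are SI (s, m, N, kg). Fore-aft is positive in the
#' direction of travel and vertical positive up. On-disk files are
#' comma-separated with a header row ('.' decimal, UTF-8), one file per trial
#' per stream.
#'
#' @name burstloco-io
NULL

# uniform-sampling check: max deviation of dt from its median, relative
.check_uniform <- function(time, what, tol = 1e-3) {
  if (length(time) < 2L) stop(sprintf("%s: need at least 2 samples", what))
  if (any(diff(time) <= 0)) stop(sprintf("%s: time must be strictly increasing", what))
  dt <- diff(time)
  dt0 <- stats::median(dt)
  if (max(abs(dt - dt0)) / dt0 > tol) {
    stop(sprintf("sampling error: %s time step varies by more than 1 part in 1e3", what))
  }
  invisible(1 / dt0)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("format error: %s is missing column(s): %s",
                 what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' Construct a force trace
#'
#' @param time sample times (s), uniform, strictly increasing.
#' @param plate plate identifier per sample (integer or character).
#' @param f_fa fore-aft force (N), positive in the direction of travel.
#' @param f_v vertical force (N), positive up, unloaded baseline 0.
#' @return A `force_trace`: data frame with attribute `rate` (Hz).
#' @export
force_trace <- function(time, plate, f_fa, f_v) {
  stopifnot(length(time) == length(f_fa), length(time) == length(f_v))
  if (length(plate) == 1L) plate <- rep(plate, length(time))
  if (!all(is.finite(f_fa)) || !all(is.finite(f_v))) {
    stop("force_trace: forces must be finite")
  }
  # per-plate validation: plates record in parallel over one time base
  rates <- vapply(split(as.numeric(time), plate), .check_uniform, 0,
                  what = "force trace")
  if (max(rates) - min(rates) > 1e-6 * rates[1]) {
    stop("sampling error: plates have different sampling rates")
  }
  rate <- rates[[1]]
  out <- data.frame(time = as.numeric(time), plate = plate,
                    f_fa = as.numeric(f_fa), f_v = as.numeric(f_v))
  attr(out, "rate") <- rate
  class(out) <- c("force_trace", "data.frame")
  out
}

#' Construct a marker trajectory
#'
#' @param time frame times (s), uniform.
#' @param x,y,z fore-aft, mediolateral, vertical position (m).
#' @param visible logical per frame; invisible frames carry NA-tolerated
#'   positions and are interpolated downstream.
#' @return A `marker_trajectory`: data frame with attribute `rate` (Hz).
#' @export
marker_trajectory <- function(time, x, y, z, visible = TRUE) {
  n <- length(time)
  if (length(visible) == 1L) visible <- rep(visible, n)
  stopifnot(length(x) == n, length(y) == n, length(z) == n, length(visible) == n)
  rate <- .check_uniform(time, "marker trajectory")
  if (n < 21L) stop("marker trajectory: need at least 21 frames")
  if (mean(!visible) >= 0.5) {
    stop("marker trajectory: fraction of invisible frames must be < 50%")
  }
  bad <- visible & !(is.finite(x) & is.finite(y) & is.finite(z))
  if (any(bad)) stop("marker trajectory: non-finite position on a visible frame")
  out <- data.frame(time = as.numeric(time), x = as.numeric(x),
                    y = as.numeric(y), z = as.numeric(z),
                    visible = as.logical(visible))
  attr(out, "rate") <- rate
  class(out) <- c("marker_trajectory", "data.frame")
  out
}

#' Construct a trial bundle
#'
#' @param trial_id,rabbit_id identifiers.
#' @param body_mass body mass M_b (kg), > 0.
#' @param force a [force_trace()].
#' @param markers a [marker_trajectory()].
#' @param collar logical, radio-collar worn during the trial.
#' @return A `trial_bundle` list.
#' @export
trial_bundle <- function(trial_id, rabbit_id, body_mass, force, markers,
                         collar = FALSE) {
  if (!is.numeric(body_mass) || length(body_mass) != 1L || !is.finite(body_mass) ||
      body_mass <= 0) {
    stop("validation error: body_mass must be a single positive number")
  }
  stopifnot(inherits(force, "force_trace"), inherits(markers, "marker_trajectory"))
  if (attr(force, "rate") <= attr(markers, "rate")) {
    stop("validation error: force sampling rate must exceed marker sampling rate")
  }
  structure(list(trial_id = as.character(trial_id),
                 rabbit_id = as.character(rabbit_id),
                 body_mass = body_mass, force = force, markers = markers,
                 collar = isTRUE(collar)),
            class = "trial_bundle")
}

#' @exportS3Method base::print
print.trial_bundle <- function(x, ...) {
  cat(sprintf("<trial_bundle %s> rabbit %s, M_b = %.3f kg, force %d Hz x %d, markers %d Hz x %d\n",
              x$trial_id, x$rabbit_id, x$body_mass,
              round(attr(x$force, "rate")), nrow(x$force),
              round(attr(x$markers, "rate")), nrow(x$markers)))
  invisible(x)
}

#' Read one trial from its force and marker CSV files
#'
#' Force CSV columns: `time_s, plate, f_fa_N, f_v_N`; marker CSV columns:
#' `time_s, x_m, y_m, z_m, visible`. Times are re-based so the earliest sample
#' of either stream (the common trigger) is t = 0.
#'
#' @param force_path,marker_path file paths.
#' @param meta named list; must contain `body_mass` (kg) and `rabbit_id`;
#'   optional `trial_id`, `collar`.
#' @param baseline_subtract if TRUE, subtract the per-plate median of the first
#'   20 ms from both force channels (plates otherwise assumed zeroed).
#' @return A [trial_bundle()].
#' @export
load_trial <- function(force_path, marker_path, meta,
                       baseline_subtract = FALSE) {
  if (!file.exists(force_path)) stop(sprintf("file not found: %s", force_path))
  if (!file.exists(marker_path)) stop(sprintf("file not found: %s", marker_path))
  if (is.null(meta$body_mass) || is.null(meta$rabbit_id)) {
    stop("validation error: meta must contain body_mass and rabbit_id")
  }
  fd <- utils::read.csv(force_path)
  .require_cols(fd, c("time_s", "plate", "f_fa_N", "f_v_N"), "force file")
  md <- utils::read.csv(marker_path)
  .require_cols(md, c("time_s", "x_m", "y_m", "z_m", "visible"), "marker file")

  t0 <- min(fd$time_s[1], md$time_s[1])
  if (baseline_subtract) {
    for (p in unique(fd$plate)) {
      i <- fd$plate == p
      j <- i & (fd$time_s - t0) <= 0.020
      fd$f_fa_N[i] <- fd$f_fa_N[i] - stats::median(fd$f_fa_N[j])
      fd$f_v_N[i] <- fd$f_v_N[i] - stats::median(fd$f_v_N[j])
    }
  }
  force <- force_trace(fd$time_s - t0, fd$plate, fd$f_fa_N, fd$f_v_N)
  markers <- marker_trajectory(md$time_s - t0, md$x_m, md$y_m, md$z_m,
                               as.logical(md$visible))
  trial_bundle(trial_id = meta$trial_id %||% basename(force_path),
               rabbit_id = meta$rabbit_id, body_mass = meta$body_mass,
               force = force, markers = markers,
               collar = isTRUE(meta$collar))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial's force and marker streams to CSV
#'
#' Inverse of [load_trial()]; numeric fields round-trip to better than 1e-9
#' relative tolerance (full double precision is written).
#'
#' @param bundle a [trial_bundle()].
#' @param force_path,marker_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_trial <- function(bundle, force_path, marker_path) {
  stopifnot(inherits(bundle, "trial_bundle"))
  fd <- data.frame(time_s = bundle$force$time, plate = bundle$force$plate,
                   f_fa_N = bundle$force$f_fa, f_v_N = bundle$force$f_v)
  md <- data.frame(time_s = bundle$markers$time, x_m = bundle$markers$x,
                   y_m = bundle$markers$y, z_m = bundle$markers$z,
                   visible = bundle$markers$visible)
  utils::write.csv(format(fd, digits = 17, scientific = TRUE, trim = TRUE),
                   force_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(format(md[1:4], digits = 17, scientific = TRUE, trim = TRUE),
                         md[5]),
                   marker_path, row.names = FALSE, quote = FALSE)
  invisible(c(force = force_path, marker = marker_path))
}

#' Read a muscle-architecture table
#'
#' Expected columns: `rabbit_id, muscle, mm_g, lf_cm, theta_deg` (belly mass in
#' g, fascicle length in cm, pennation angle in degrees). Values stay in these
#' units; conversion to SI happens only inside the power computation.
#'
#' @param path CSV path.
#' @return Data frame of validated muscle records (possibly 0 rows, with a
#'   warning).
#' @export
load_muscle_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  .require_cols(df, c("rabbit_id", "muscle", "mm_g", "lf_cm", "theta_deg"),
                "muscle table")
  if (nrow(df) == 0L) {
    warning("muscle table is empty")
    return(df)
  }
  if (any(df$theta_deg < 0 | df$theta_deg >= 90)) {
    stop("validation error: pennation angle must lie in [0, 90) degrees")
  }
  if (any(df$mm_g <= 0) || any(df$lf_cm <= 0)) {
    stop("validation error: muscle mass and fascicle length must be positive")
  }
  df
}

#' Classify age from body mass
#'
#' Individuals under 1 kg are juveniles; 1 kg and above are adults (the
#' boundary is assigned to adults). Pure function of mass.
#'
#' @param body_mass body mass (kg).
#' @param cutoff juvenile/adult mass cutoff (kg).
#' @return Character vector, `"juvenile"` or `"adult"`.
#' @export
age_class <- function(body_mass, cutoff = 1.0) {
  ifelse(body_mass < cutoff, "juvenile", "adult")
}

#' Read a cohort table
#'
#' Expected columns `rabbit_id, body_mass_kg`; optional `collared,
#' survival_days`. Derives `age_class` from body mass; duplicate rabbit ids are
#' rejected.
#'
#' @param path CSV path.
#' @return Data frame, one row per individual.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  .require_cols(df, c("rabbit_id", "body_mass_kg"), "cohort table")
  if (anyDuplicated(df$rabbit_id)) {
    stop("validation error: duplicate rabbit_id in cohort table")
  }
  if (any(df$body_mass_kg <= 0)) stop("validation error: body mass must be positive")
  df$age_class <- age_class(df$body_mass_kg)
  df
}
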