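#' @title Hindlimb extensor muscle power capacity from architecture
#'
#' @description
#' Architectural estimate of peak instantaneous hindlimb extensor power:
#' physiological cross-sectional area `PCSA = MM cos(theta) / (L_F rho)` with
#' muscle density rho = 1.06 g/cm^3; maximum isometric force
#' `F_max = sigma PCSA` with sigma = 30 N/cm^2; maximum shortening velocity
#' `V_max = 6.3` fascicle lengths per second (fast MHC-2X fibres); peak power
#' `P_peak = 0.1 F_max V_max`; and total capacity `P_musc = 2 sum(P_peak)`,
#' the doubling representing simultaneous extension of both hindlimbs in the
#' half-bounding stride. Inputs stay in the conventional g/cm units so the
#' formulas read as usually printed; conversion to SI happens only inside the
#' power step.
#'
#' @name burstloco-muscle
NULL

#' Physiological cross-sectional area
#'
#' @param mm muscle belly mass MM (g), > 0.
#' @param theta pennation angle (degrees), in [0, 90).
#' @param lf fascicle length L_F (cm), > 0.
#' @param rho muscle density (g/cm^3), default 1.06.
#' @return PCSA (cm^2).
#' @export
pcsa <- function(mm, theta, lf, rho = 1.06) {
  if (any(theta < 0 | theta >= 90)) {
    stop("domain error: pennation angle must lie in [0, 90) degrees")
  }
  if (any(mm <= 0) || any(lf <= 0) || rho <= 0) {
    stop("domain error: mass, fascicle length and density must be > 0")
  }
  mm * cos(theta * pi / 180) / (lf * rho)
}

#' Maximum isometric force
#'
#' @param pcsa_cm2 PCSA (cm^2), > 0.
#' @param sigma maximum isometric stress (N/cm^2), default 30.
#' @return F_max (N).
#' @export
max_isometric_force <- function(pcsa_cm2, sigma = 30) {
  if (any(pcsa_cm2 <= 0)) stop("domain error: PCSA must be > 0")
  sigma * pcsa_cm2
}

#' Peak instantaneous muscle power
#'
#' `V_max = vmax_per_length * L_F` (fascicle lengths/s, converted cm/s ->
#' m/s); `P_peak = 0.1 * F_max * V_max`.
#'
#' @param f_max maximum isometric force (N), > 0.
#' @param lf fascicle length (cm), > 0.
#' @param vmax_per_length maximum shortening velocity in fascicle lengths per
#'   second, default 6.3.
#' @return P_peak (W).
#' @export
peak_muscle_power <- function(f_max, lf, vmax_per_length = 6.3) {
  if (any(f_max <= 0) || any(lf <= 0) || vmax_per_length <= 0) {
    stop("domain error: inputs must be > 0")
  }
  v_max <- vmax_per_length * lf / 100        # cm/s -> m/s
  0.1 * f_max * v_max
}

#' Average site-level pennation measurements into one representative angle
#'
#' Raw pennation is measured at several random locations through the belly;
#' the representative angle entering the PCSA formula is the mean angle (the
#' cosine is then taken of the mean, matching the single-theta formula).
#'
#' @param angles site measurements (degrees).
#' @return Mean angle (degrees).
#' @export
mean_pennation <- function(angles) {
  if (any(angles < 0 | angles >= 90)) {
    stop("domain error: pennation angles must lie in [0, 90) degrees")
  }
  mean(angles)
}

#' Total hindlimb extensor power capacity
#'
#' Runs the full chain per muscle row and totals
#' `P_musc = 2 * sum(P_peak)`; each table row is summed as listed (both heads
#' of a two-headed muscle count separately).
#'
#' @param muscles data frame with columns `muscle, mm_g, lf_cm, theta_deg`
#'   (e.g. from [load_muscle_table()]), for one individual.
#' @param rho,sigma,vmax_per_length constants of the chain.
#' @return List with `p_musc` (W) and `per_muscle` (data frame with `pcsa_cm2,
#'   f_max_N, v_max_ms, p_peak_W`).
#' @export
total_hindlimb_power <- function(muscles, rho = 1.06, sigma = 30,
                                 vmax_per_length = 6.3) {
  if (is.null(nrow(muscles)) || nrow(muscles) < 1L) {
    stop("validation error: need at least one muscle")
  }
  a <- pcsa(muscles$mm_g, muscles$theta_deg, muscles$lf_cm, rho)
  f <- max_isometric_force(a, sigma)
  p <- peak_muscle_power(f, muscles$lf_cm, vmax_per_length)
  per <- data.frame(muscle = muscles$muscle, pcsa_cm2 = a, f_max_N = f,
                    v_max_ms = vmax_per_length * muscles$lf_cm / 100,
                    p_peak_W = p)
  list(p_musc = 2 * sum(p), per_muscle = per)
}

#' Per-individual P_musc from a multi-individual muscle table
#'
#' @param muscles data frame with a `rabbit_id` column plus the architecture
#'   columns of [total_hindlimb_power()].
#' @param ... passed to [total_hindlimb_power()].
#' @return Data frame: `rabbit_id`, `p_musc_W`, `n_muscles`.
#' @export
muscle_power_table <- function(muscles, ...) {
  out <- lapply(split(muscles, muscles$rabbit_id), function(d) {
    data.frame(rabbit_id = d$rabbit_id[1],
               p_musc_W = total_hindlimb_power(d, ...)$p_musc,
               n_muscles = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
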