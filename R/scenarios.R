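#' @title Constant-acceleration escape scenarios
#'
#' @description
#' Translates fitted peak-acceleration curves into ecological performance
#' predictions under constant acceleration from a static start: distance
#' covered in the first second of sprinting, time to reach a refuge, and the
#' number of strides needed to reach top recorded speed, compared between a
#' representative juvenile and adult.
#'
#' @name burstloco-scenarios
NULL

#' Run the three constant-acceleration scenarios
#'
#' Under constant acceleration a from rest: distance in the first second is
#' `a/2`; time to a refuge at distance d is `sqrt(2 d / a)`; strides to reach
#' speed v are `ceiling((v / a) / stride_duration)`. Ratios compare juvenile
#' to adult: distance ratio `a_juv/a_adult`, time ratio
#' `sqrt(a_adult/a_juv)` (so distance ratio x time ratio^2 = 1 exactly), and
#' the stride difference is adult strides minus juvenile strides.
#'
#' @param a_juv,a_adult constant accelerations (m/s^2), > 0.
#' @param refuge refuge distance (m), default 10.
#' @param top_speed top recorded speed (m/s), default 11.1.
#' @param stride_duration stride period (s) used for the stride-count
#'   scenario; this quantity is not fixed by theory, so it should come from
#'   the processed dataset at hand (the scenario most sensitive to this
#'   choice). NULL skips the stride scenario.
#' @return A `scenario_result`: list of per-age vectors `distance_1s` (m),
#'   `time_to_refuge` (s), `strides_to_top` (count or NA), and `ratios`
#'   (`distance_ratio`, `time_ratio`, `stride_difference`).
#' @export
run_scenarios <- function(a_juv, a_adult, refuge = 10, top_speed = 11.1,
                          stride_duration = NULL) {
  if (a_juv <= 0 || a_adult <= 0) stop("domain error: accelerations must be > 0")
  if (refuge <= 0 || top_speed <= 0) stop("domain error: refuge and top_speed must be > 0")
  a <- c(juvenile = a_juv, adult = a_adult)
  dist1 <- a / 2
  t_ref <- sqrt(2 * refuge / a)
  if (!is.null(stride_duration)) {
    if (stride_duration <= 0) stop("domain error: stride_duration must be > 0")
    strides <- ceiling((top_speed / a) / stride_duration)
  } else {
    strides <- c(juvenile = NA_real_, adult = NA_real_)
  }
  structure(list(distance_1s = dist1, time_to_refuge = t_ref,
                 strides_to_top = strides,
                 ratios = c(distance_ratio = unname(a["juvenile"] / a["adult"]),
                            time_ratio = unname(sqrt(a["adult"] / a["juvenile"])),
                            stride_difference = unname(strides["adult"] - strides["juvenile"]))),
            class = "scenario_result")
}

#' @exportS3Method base::print
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  cat(sprintf("  distance in 1 s : juvenile %.2f m, adult %.2f m (ratio %.0f%%)\n",
              x$distance_1s["juvenile"], x$distance_1s["adult"],
              100 * x$ratios["distance_ratio"]))
  cat(sprintf("  time to refuge  : juvenile %.2f s, adult %.2f s (ratio %.0f%%)\n",
              x$time_to_refuge["juvenile"], x$time_to_refuge["adult"],
              100 * x$ratios["time_ratio"]))
  if (is.finite(x$strides_to_top["juvenile"])) {
    cat(sprintf("  strides to top  : juvenile %d, adult %d (difference %d)\n",
                as.integer(x$strides_to_top["juvenile"]),
                as.integer(x$strides_to_top["adult"]),
                as.integer(x$ratios["stride_difference"])))
  }
  invisible(x)
}

#' Scenarios from a fitted peak-acceleration quadratic
#'
#' Evaluates the per-individual-peak quadratic at representative juvenile and
#' adult masses and runs [run_scenarios()].
#'
#' @param fit a [fit_quadratic()] result for peak acceleration.
#' @param juv_mass,adult_mass representative masses (kg), defaults 0.8 and
#'   1.2.
#' @param ... passed to [run_scenarios()].
#' @return A `scenario_result` with an added `accelerations` element.
#' @export
scenarios_from_fit <- function(fit, juv_mass = 0.8, adult_mass = 1.2, ...) {
  a_j <- predict_accel(fit, juv_mass)
  a_a <- predict_accel(fit, adult_mass)
  out <- run_scenarios(a_j, a_a, ...)
  out$accelerations <- c(juvenile = a_j, adult = a_a)
  out
}
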