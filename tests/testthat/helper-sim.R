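# shared fixtures built in code

# trapezoidal integral, independent of the package internals
trapz_ref <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

# a plain single-plate force trace: F_FA = f_fa N and F_V = f_v N over
# [on, off], zero elsewhere, 500 Hz
boxcar_trace <- function(f_fa, f_v, on = 0.10, off = 0.35, total = 0.45,
                         rate = 500) {
  tt <- seq(0, total, by = 1 / rate)
  sel <- tt >= on - 1e-9 & tt <= off + 1e-9
  force_trace(tt, 1L, ifelse(sel, f_fa, 0), ifelse(sel, f_v, 0))
}

# per-trial metrics table for stats tests, straight from the cohort generator
cohort_quad_data <- function(seed, ...) {
  co <- simulate_cohort(cohort_sim_params(seed = seed, ...))
  list(co = co,
       a = data.frame(mass = co$trials$body_mass_kg, response = co$trials$a_com,
                      rabbit_id = co$trials$rabbit_id),
       v = data.frame(mass = co$trials$body_mass_kg, response = co$trials$v_esc,
                      rabbit_id = co$trials$rabbit_id))
}
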