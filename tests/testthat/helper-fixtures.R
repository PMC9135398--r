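# shared fixtures for the suite

# reference passive circuit of the granule-cell-like multicompartment
# reduction: components (tau0, R0, tau1, R1) and the mapped circuit
ref_components <- function() {
  structure(list(n = 2L, tau_ms = c(15.1, 0.18), R_MOhm = c(119.2, 12.3),
                 v_mV = c(15.1, 0.18) * NA, I_ext_pA = 1, rss = 0,
                 n_samples = NA_integer_, ill_separated = FALSE),
            class = "cc_exp_components")
}

ref_circuit <- function() two_compartment(13.0, 1158.0, 15.5, 113.7, 132.8)

# the hardware-demo RC circuit
demo_rc <- function() rc_circuit(99.4, 112.3)

# step response of a clamped (or plain) RC, single-exponential fit
fit_rc_step <- function(model, cfg = NULL, step_pA = -100, step_ms = 250,
                        sim_dt = 0.001, record_dt = 0.05) {
  onset <- 20
  stim <- stim_step(step_pA, onset, onset + step_ms)
  tr <- if (is.null(cfg))
    integrate_model(model, stim, onset + step_ms, sim_dt,
                    record_dt_ms = record_dt)
  else run_clamped(model, cfg, stim, onset + step_ms, sim_dt,
                   record_dt_ms = record_dt)
  w <- trace_window(tr, onset, onset + step_ms)
  seg <- cc_trace(data.frame(time_ms = w$time_ms - w$time_ms[1],
                             V_mV = w$V_mV - w$V_mV[1]), trace_dt(w))
  fit_exponentials(seg, step_pA, 1, window_ms = step_ms)
}

# analytic two-exponential charging curve as a trace
analytic_charging <- function(tau0, R0, tau1, R1, I_pA, dt = 0.05,
                              t_max = 100) {
  t <- seq(0, t_max, by = dt)
  v <- I_pA * (R0 * (1 - exp(-t / tau0)) + R1 * (1 - exp(-t / tau1))) / 1000
  cc_trace(data.frame(time_ms = t, V_mV = v), dt)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
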