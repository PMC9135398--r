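test_that("controller update implements the discrete feedback law", {
  # Ct = Cc: prefactor vanishes
  cfg <- clamp_config(100, 100, 20)
  st <- clamp_state_init(-60)
  expect_equal(capclamp_update(-55, st, cfg)$I_dyn_pA, 0)

  # (Cc-Ct)/Ct * Cc * dV/dt: 1 * 100 pF * 20 mV/ms = 2000 pA
  cfg <- clamp_config(100, 50, 20)
  st <- clamp_state_init(0)
  expect_equal(capclamp_update(1, st, cfg)$I_dyn_pA, 2000)

  # increase: (100-200)/200 * (0 - 100) = +50 pA
  cfg <- clamp_config(100, 200, 20)
  st <- clamp_state_init(0)
  st$I_prev1_pA <- 100
  expect_equal(capclamp_update(0, st, cfg)$I_dyn_pA, 50)

  expect_error(capclamp_update(NaN, st, cfg), "non-finite")
  expect_error(clamp_config(100, -1, 20), "positive")
})

test_that("membrane-current estimate matches analytic RC currents", {
  expect_equal(estimate_membrane_current(-60, -60, 0, 100, 0.05), 0)
  expect_equal(estimate_membrane_current(-60.5, -60, 0, 112.3, 0.05), -1123)

  # unclamped RC mid-charging: estimate = I_ext + I_R up to O(dt/tau)
  R <- 100; C <- 100; tau <- 10; dt <- 0.05
  t1 <- 5
  V <- function(t) -100 * R / 1000 * (1 - exp(-t / tau))
  est <- estimate_membrane_current(V(t1 + dt), V(t1), 0, C, dt)
  truth <- -100 - V(t1) * 1000 / R
  expect_lt(abs(est - truth) / abs(truth), 2 * dt / tau)
})

test_that("clamping at the cell's own capacitance leaves dynamics untouched", {
  wb <- wb_neuron()
  stim <- stim_step(60, 20, 220)
  cfg <- clamp_config(150, 150, 20)
  tr_c <- run_clamped(wb, cfg, stim, 220, 0.001, record_dt_ms = 0.05)
  tr_u <- integrate_model(wb, stim, 220, 0.001, record_dt_ms = 0.05)
  expect_lt(max(abs(tr_c$V_mV - tr_u$V_mV)), 1e-9)
  expect_equal(max(abs(tr_c$Idyn_pA)), 0)
})

test_that("clamped RC reproduces the step response of the target circuit", {
  Cc <- 112.3; R <- 99.4
  rc <- rc_circuit(R, Cc)
  stim <- stim_step(-100, 20, 270)
  for (Ct in c(67.4, 168.45)) {
    cfg <- clamp_config(Cc, Ct, 20)   # dt/tau_t < 0.01
    tr_c <- run_clamped(rc, cfg, stim, 270, 0.001, record_dt_ms = 0.05)
    tr_t <- integrate_model(rc_circuit(R, Ct), stim, 270, 0.001,
                            record_dt_ms = 0.05)
    dV <- abs(-100 * R / 1000)
    expect_lt(max(abs(tr_c$V_mV - tr_t$V_mV)) / dV, 0.01)
    # steady-state amplitude is invariant under clamping
    ss_c <- mean(trace_window(tr_c, 250, 269)$V_mV)
    expect_rel(abs(ss_c), dV, 0.01)
  }
})

test_that("one-cycle delay mode converges to zero-delay with rate 1/f_dyn", {
  rc <- demo_rc()
  stim <- stim_step(-100, 10, 100)
  dev <- vapply(c(20, 40), function(fd) {
    z <- run_clamped(rc, clamp_config(112.3, 67.4, fd), stim, 100, 0.00125)
    o <- run_clamped(rc, clamp_config(112.3, 67.4, fd,
                                      delay_mode = "one-cycle"),
                     stim, 100, 0.00125)
    max(abs(z$V_mV - o$V_mV))
  }, numeric(1))
  expect_gt(dev[1], 0)
  expect_lt(dev[2] / dev[1], 0.7)   # halves when f_dyn doubles
  expect_gt(dev[2] / dev[1], 0.3)
})

test_that("clamping a two-compartment cell changes only the near capacitance", {
  circ <- ref_circuit()
  Cn <- circ$Cn_pF
  for (k in c(0.6, 3)) {
    cfg <- clamp_config(Cn, k * Cn, 100)
    meas <- measure_capacitance(circ, clamp = cfg, sim_dt_ms = 0.002,
                                record_dt_ms = 0.05,
                                protocol = build_pulse_protocol(
                                  R_estimate_MOhm = dc_input_resistance(circ),
                                  n_pulses = 3))
    expect_rel(meas$circuit$Cn_pF, k * Cn, 0.05)
    expect_rel(meas$circuit$Cf_pF, circ$Cf_pF, 0.05)
    expect_rel(meas$circuit$Rf_MOhm, circ$Rf_MOhm, 0.05)
  }
})

test_that("fast clamping matches a physically altered capacitance in spiking", {
  wb <- wb_neuron()
  stim <- stim_step(60, 100, 1100)
  cfg <- clamp_config(150, 90, 100, current_limit_pA = Inf)
  tr_c <- run_clamped(wb, cfg, stim, 1100, 0.001, record_dt_ms = 0.01)
  tr_t <- integrate_model(wb_with_capacitance(wb, 90), stim, 1100, 0.001,
                          record_dt_ms = 0.01)
  f_c <- firing_frequency(tr_c, c(100, 1100))
  f_t <- firing_frequency(tr_t, c(100, 1100))
  expect_rel(f_c, f_t, 0.03)
  w_c <- mean_spike_features(tr_c, c(100, 1100))$mean$width_ms
  w_t <- mean_spike_features(tr_t, c(100, 1100))$mean$width_ms
  expect_rel(w_c, w_t, 0.03)
})

test_that("compiled clamp loop agrees with the R reference controller", {
  # attach the R-level controller through the external-current contract at
  # the clamp rate and compare with the built-in compiled clamp
  rc <- rc_circuit(100, 100)
  cfg <- clamp_config(100, 60, 20)
  stim <- stim_step(-80, 5, 50)
  env <- new.env()
  env$state <- clamp_state_init(0)
  env$I <- 0
  src <- function(t, V) {
    upd <- capclamp_update(V, env$state, cfg)
    env$state <- upd$state
    upd$I_dyn_pA
  }
  tr_r <- integrate_model(rc, stim, 50, 0.05, record_dt_ms = 0.05,
                          external_current_source = src)
  tr_c <- run_clamped(rc, cfg, stim, 50, 0.05, record_dt_ms = 0.05)
  expect_lt(max(abs(tr_r$V_mV - tr_c$V_mV)), 1e-9)
})

test_that("unstable clamp settings are flagged, not silent", {
  rc <- rc_circuit(100, 100)
  # tight current limit forces persistent clipping
  cfg <- clamp_config(100, 20, 20, current_limit_pA = 50)
  expect_warning(
    tr <- run_clamped(rc, cfg, stim_step(-100, 5, 95), 100, 0.001),
    "unstable")
  expect_true(attr(tr, "unstable"))
  expect_gt(attr(tr, "clip_count"), 0)
})
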