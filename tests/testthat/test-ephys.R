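test_that("spike detection finds peaks above the depolarized mean", {
  dt <- 0.05
  t <- seq(0, 500, by = dt)
  flat <- cc_trace(data.frame(time_ms = t, V_mV = rep(-60, length(t))), dt)
  expect_length(detect_spikes(flat), 0)

  centers <- seq(50, 450, length.out = 7)
  V <- rep(-60, length(t))
  for (ct in centers) V <- V + 30 * exp(-(t - ct)^2 / (2 * 0.5^2))
  bumps <- cc_trace(data.frame(time_ms = t, V_mV = V), dt)
  sp <- detect_spikes(bumps)
  expect_length(sp, 7)
  expect_lt(max(abs(sp - centers)), 0.1)
  expect_error(detect_spikes(flat, window_ms = c(600, 700)), "window")
})

test_that("spike features follow their geometric definitions", {
  # symmetric triangular spike, height 40 mV, total width 1 ms at base
  dt <- 0.01
  t <- seq(0, 20, by = dt)
  V <- rep(-60, length(t))
  apex <- 10
  tri <- pmax(0, 1 - abs(t - apex) / 0.5) * 40
  V <- V + tri
  tr <- cc_trace(data.frame(time_ms = t, V_mV = V), dt)
  ft <- spike_features(tr, apex, deriv_crossing_mV_ms = 10)
  # derivative is 80 mV/ms on the flank; crossing sits at the triangle base
  expect_lt(abs(ft$threshold_mV - (-60)), 1.5)
  expect_lt(abs(ft$width_ms - 0.5), 0.05)
  expect_error(spike_features(tr, 1), "pre-window")
})

test_that("square-root f-I fits recover exact synthetic parameters", {
  I <- seq(90, 300, length.out = 10)
  f <- 2 * sqrt(pmax(I - 100, 0))
  ft <- fit_fi(I, f)
  expect_rel(ft$gain, 2, 1e-6)
  expect_lt(abs(ft$Irheo_pA - 100), 1e-3)
  expect_error(fit_fi(c(100, 150, 200, 250), c(10, 30, 20, 40)),
               "non-monotonically")
  expect_error(fit_fi(c(100, 150), c(0, 10)), "4 points")
})

test_that("gain scales inversely with capacitance at constant rheobase", {
  p <- gain_capacitance_prediction(3.8, 150, 150)
  expect_equal(p$gain_predicted, 3.8)
  expect_rel(gain_capacitance_prediction(3.8, 150, 75)$gain_predicted, 7.6,
             1e-12)
  expect_rel(abs(gain_capacitance_prediction(3.8, 150, 150)$dgain_per_10pF),
             0.25, 0.02)
  expect_rel(abs(gain_capacitance_prediction(1.8, 127, 127)$dgain_per_10pF),
             0.14, 0.02)
})

test_that("hypothetical spike rescaling is linear and invertible", {
  dt <- 0.01
  t <- seq(0, 20, by = dt)
  V <- -60 + 40 * exp(-(t - 10)^2 / 0.3)
  tr <- cc_trace(data.frame(time_ms = t, V_mV = V), dt)
  same <- hypothetical_spike(tr, 100, 100, 10)
  expect_equal(same$V_mV, tr$V_mV)
  dbl <- hypothetical_spike(tr, 100, 50, 10)
  V0 <- approx(t, V, 7)$y
  expect_lt(max(abs((dbl$V_mV - V0) - 2 * (V - V0))), 1e-9)
  back <- hypothetical_spike(dbl, 50, 100, 10)
  expect_lt(max(abs(back$V_mV - V)), 1e-12)
  expect_error(hypothetical_spike(tr, 100, 50, 1), "pre-spike")
})

test_that("charge metrics scale with capacitance and cover the sodium load", {
  wb <- wb_neuron()
  stim <- stim_step(60, 100, 700)
  out <- lapply(c(90, 210), function(C) {
    tr <- integrate_model(wb_with_capacitance(wb, C), stim, 700, 0.001,
                          record_dt_ms = 0.01, record_currents = TRUE)
    sp <- detect_spikes(tr, window_ms = c(400, 700))
    charge_metrics(tr, C, sp[2])
  })
  q90 <- out[[1]]; q210 <- out[[2]]
  expect_gt(q210$Qplus_pC, q90$Qplus_pC)
  expect_gt(q210$QNa_pC, q90$QNa_pC)
  expect_gt(q90$QNa_pC, q90$Qplus_pC)
  expect_gt(q210$QNa_pC, q210$Qplus_pC)
  # Q+ = C * dV by definition
  expect_equal(q90$Qplus_pC, 90 * q90$deltaV_AP_mV / 1000, tolerance = 1e-12)
})

test_that("integration ratio matches closed-form superposition", {
  rc <- rc_circuit(100, 100)   # tau = 10 ms
  st <- stim_pulse_train(50, 3, 5, 5, onset_ms = 50)
  tr <- integrate_model(rc, st, 150, 0.005, record_dt_ms = 0.01)
  r <- integration_ratio(tr, st)
  step_resp <- function(t, on) ifelse(t > on, 5 * (1 - exp(-(t - on) / 10)), 0)
  resp <- function(t) sum(step_resp(t, 50 + (0:4) * 8) -
                            step_resp(t, 53 + (0:4) * 8))
  expect_lt(abs(r - resp(85) / resp(53)), 1e-6)
  expect_gt(r, 1)

  # full decay between pulses: ratio -> 1
  rc_fast <- rc_circuit(100, 10)
  st2 <- stim_pulse_train(50, 3, 50, 5, onset_ms = 50)
  tr2 <- integrate_model(rc_fast, st2, 350, 0.005, record_dt_ms = 0.01)
  expect_lt(abs(integration_ratio(tr2, st2) - 1), 1e-6)

  # a spiking trace is rejected
  wb <- wb_neuron()
  st3 <- stim_pulse_train(600, 3, 5, 5, onset_ms = 50)
  tr3 <- integrate_model(wb, st3, 150, 0.001, record_dt_ms = 0.05)
  expect_error(integration_ratio(tr3, st3), "sub-threshold")
})

test_that("temporal integration grows with clamped capacitance", {
  circ <- ref_circuit()
  st <- stim_pulse_train(30, 3, 5, 5, onset_ms = 50)
  ratios <- vapply(c(0.6, 3), function(k) {
    cfg <- clamp_config(circ$Cn_pF, k * circ$Cn_pF, 20)
    tr <- run_clamped(circ, cfg, st, 150, 0.005, record_dt_ms = 0.05)
    integration_ratio(tr, st)
  }, numeric(1))
  expect_gt(ratios[2], ratios[1])
})

test_that("clamped RC impedance: DC limit, identity and simulation check", {
  z0 <- clamped_rc_impedance(99.4, 112.3, 336.9, 20, 1e-9)
  expect_rel(z0$Z_clamped_MOhm, 99.4, 1e-6)
  expect_rel(z0$Z_target_MOhm, 99.4, 1e-6)

  # Ct = Cc: controller inactive, impedance equals the cell's own
  fr <- c(10, 100, 1000, 5000)
  zi <- clamped_rc_impedance(99.4, 112.3, 112.3, 20, fr)
  expect_lt(max(abs(zi$Z_clamped_MOhm / zi$Z_cell_MOhm - 1)), 1e-9)

  expect_error(clamped_rc_impedance(99.4, 112.3, 336.9, 20, 10000),
               "Nyquist")

  # analytic closed loop vs sinusoid-driven simulation: < 1% below f_dyn/10
  for (Ct in c(67.4, 336.9)) {
    cfg <- clamp_config(112.3, Ct, 20)
    for (f in c(100, 1000)) {
      zs <- measure_impedance(demo_rc(), f, clamp = cfg, sim_dt_ms = 0.0025)
      za <- clamped_rc_impedance(99.4, 112.3, Ct, 20, f)$Z_clamped_MOhm
      expect_rel(zs, za, 0.01)
    }
  }
})

test_that("spike shape varies monotonically with capacitance", {
  wb <- wb_neuron()
  stim <- stim_step(60, 100, 800)
  feats <- lapply(c(75, 150, 225), function(C) {
    tr <- integrate_model(wb_with_capacitance(wb, C), stim, 800, 0.001,
                          record_dt_ms = 0.01)
    mean_spike_features(tr, c(100, 800))$mean
  })
  peaks <- vapply(feats, `[[`, numeric(1), "peak_mV")
  widths <- vapply(feats, `[[`, numeric(1), "width_ms")
  ahps <- vapply(feats, `[[`, numeric(1), "AHP_mV")
  expect_true(all(diff(peaks) < 0))
  expect_true(all(diff(widths) > 0))
  expect_true(all(diff(ahps) > 0))  # AHP shallower at higher C
})
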