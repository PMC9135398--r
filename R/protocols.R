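#' RC-circuit clamp demonstration
#'
#' Clamps an RC circuit at a sweep of target capacitances, measures the step
#' response of each (single-exponential fit giving tau, deltaV, R and the
#' apparent capacitance) and decomposes the deposited charge into the
#' apparent part (leak + stimulus) and the total including the clamp current.
#'
#' @param R_MOhm,C_pF circuit parameters.
#' @param Ct_factors sweep of target capacitances as multiples of `C_pF`.
#' @param f_dyn_kHz clamp frequency (kHz).
#' @param step_pA amplitude of the test step (pA).
#' @param step_ms step duration (ms).
#' @param sim_dt_ms integration step (ms).
#' @return data frame with one row per target: `Ct_pF`, `tau_ms`,
#'   `deltaV_mV`, `R_meas_MOhm`, `C_meas_pF`, `dQ_apparent_pC`,
#'   `dQ_total_pC`.
#' @export
run_rc_demo <- function(R_MOhm = 99.4, C_pF = 112.3,
                        Ct_factors = c(0.6, 1, 1.5, 2, 3),
                        f_dyn_kHz = 20, step_pA = -100, step_ms = 250,
                        sim_dt_ms = 0.001) {
  model <- rc_circuit(R_MOhm, C_pF)
  onset <- 20
  dur <- onset + step_ms + 50
  stim <- stim_step(step_pA, onset_ms = onset, offset_ms = onset + step_ms)
  rows <- lapply(Ct_factors, function(fac) {
    Ct <- fac * C_pF
    cfg <- clamp_config(C_pF, Ct, f_dyn_kHz)
    tr <- run_clamped(model, cfg, stim, dur, sim_dt_ms,
                      record_dt_ms = 1 / f_dyn_kHz)
    w <- trace_window(tr, onset, onset + step_ms)
    seg <- cc_trace(data.frame(time_ms = w$time_ms - w$time_ms[1],
                               V_mV = w$V_mV - w$V_mV[1]), trace_dt(w))
    fit <- fit_exponentials(seg, step_pA, 1, window_ms = step_ms)
    # charge bookkeeping over the step: apparent = leak + stimulus
    IR <- -w$V_mV * 1000 / R_MOhm
    dQ_app <- cumsum(IR + w$Iext_pA) * trace_dt(w) / 1000    # pC
    dQ_tot <- cumsum(IR + w$Iext_pA + w$Idyn_pA) * trace_dt(w) / 1000
    n_ss <- length(dQ_app)
    ss_idx <- round(0.9 * n_ss):n_ss
    data.frame(Ct_pF = Ct, tau_ms = fit$tau_ms[1],
               deltaV_mV = fit$v_mV[1], R_meas_MOhm = fit$R_MOhm[1],
               C_meas_pF = capacitance_isopotential(fit$tau_ms[1],
                                                    fit$R_MOhm[1]),
               dQ_apparent_pC = mean(dQ_app[ss_idx]),
               dQ_total_pC = mean(dQ_tot[ss_idx]))
  })
  do.call(rbind, rows)
}

#' Wang-Buzsaki clamp characterization
#'
#' For each capacitance, runs a control simulation (capacitance physically
#' altered) and a clamped simulation (original capacitance, clamp targeting
#' the same value): firing frequency and mean spike features at a fixed test
#' current, and optionally the f-I curve fit.
#'
#' @param capacitances_pF capacitances to test (pF).
#' @param Cc_pF original capacitance the clamp starts from (pF).
#' @param f_dyn_kHz clamp frequency (kHz).
#' @param I_test_pA test step current (pA, default 60).
#' @param with_fi also measure f-I gain and rheobase per capacitance.
#' @param step_ms test/f-I step duration (ms).
#' @param sim_dt_ms integration step (ms).
#' @param record_dt_ms recording interval for spike analysis (ms); 0.01 ms
#'   keeps sub-sample spike-width interpolation accurate.
#' @param model base [wb_neuron()].
#' @return data frame with one row per (capacitance, mode) combination.
#' @export
run_wb_characterization <- function(capacitances_pF = c(90, 150, 210),
                                    Cc_pF = 150, f_dyn_kHz = 20,
                                    I_test_pA = 60, with_fi = FALSE,
                                    step_ms = 1000, sim_dt_ms = 0.001,
                                    record_dt_ms = 0.01,
                                    model = wb_neuron()) {
  base <- wb_with_capacitance(model, Cc_pF)
  onset <- 100
  dur <- onset + step_ms
  stim <- stim_step(I_test_pA, onset_ms = onset, offset_ms = dur)
  one_run <- function(C, mode) {
    if (mode == "control") {
      m <- wb_with_capacitance(model, C)
      tr <- integrate_model(m, stim, dur, sim_dt_ms,
                            record_dt_ms = record_dt_ms)
      cl <- NULL; m_fi <- m
    } else {
      cl <- clamp_config(Cc_pF, C, f_dyn_kHz)
      tr <- run_clamped(base, cl, stim, dur, sim_dt_ms,
                        record_dt_ms = record_dt_ms)
      m_fi <- base
    }
    f <- firing_frequency(tr, c(onset, dur))
    feats <- tryCatch(mean_spike_features(tr, c(onset, dur)),
                      error = function(e) NULL)
    row <- data.frame(C_pF = C, mode = mode, f_Hz = f,
                      hAP_mV = NA_real_, wAP_ms = NA_real_,
                      AHP_mV = NA_real_, tAHP_ms = NA_real_,
                      gain = NA_real_, Irheo_pA = NA_real_)
    if (!is.null(feats)) {
      row$hAP_mV <- feats$mean$height_mV
      row$wAP_ms <- feats$mean$width_ms
      row$AHP_mV <- feats$mean$AHP_mV
      row$tAHP_ms <- feats$mean$t_AHP_ms
    }
    if (with_fi) {
      fi <- fi_curve(m_fi, clamp = cl, step_ms = step_ms,
                     sim_dt_ms = sim_dt_ms)
      if (!is.null(fi$fit)) {
        row$gain <- fi$fit$gain
        row$Irheo_pA <- fi$fit$Irheo_pA
      }
    }
    row
  }
  rows <- list()
  for (C in capacitances_pF) {
    rows[[length(rows) + 1]] <- one_run(C, "control")
    if (C != Cc_pF)
      rows[[length(rows) + 1]] <- one_run(C, "clamped")
  }
  do.call(rbind, rows)
}

#' Verification of a clamped capacitance measurement
#'
#' Clamps a two-compartment (or cable) cell at `k`-fold its near capacitance
#' for each factor in the sweep, reruns the pulse-protocol measurement, maps
#' the fitted components to the circuit with the matching `k`, and compares
#' measured against predicted components (prediction: `Cn -> k*Cn`, other
#' parameters at their true values).
#'
#' @param circuit a [two_compartment()] model (ground truth).
#' @param k_sweep clamping factors.
#' @param f_dyn_kHz clamp frequency (kHz).
#' @param sim_dt_ms,record_dt_ms simulation and sampling intervals (ms).
#' @param n_pulses number of protocol pulses (20 in the full protocol; fewer
#'   shortens the run for noiseless checks).
#' @return list with `results` (data frame per k: measured and predicted
#'   components and circuit parameters) and `r_squared` per observable.
#' @export
run_measurement_verification <- function(circuit, k_sweep = c(0.6, 1, 2, 3),
                                         f_dyn_kHz = 20, sim_dt_ms = 0.005,
                                         record_dt_ms = 0.05, n_pulses = 4) {
  stopifnot(inherits(circuit, "cc_two_compartment"))
  Cn <- circuit$Cn_pF
  protocol <- build_pulse_protocol(
    R_estimate_MOhm = dc_input_resistance(circuit), n_pulses = n_pulses)
  rows <- lapply(k_sweep, function(k) {
    clamp <- if (k == 1) NULL else
      clamp_config(Cn, k * Cn, f_dyn_kHz)
    meas <- measure_capacitance(circuit, clamp = clamp, protocol = protocol,
                                sim_dt_ms = sim_dt_ms,
                                record_dt_ms = record_dt_ms, k = k)
    pred_circ <- two_compartment(k * Cn, circuit$Rn_MOhm, circuit$Ra_MOhm,
                                 circuit$Cf_pF, circuit$Rf_MOhm, k = k)
    pred <- components_from_circuit(pred_circ)
    fit2 <- meas$fits[[2]]
    circ <- meas$circuit
    data.frame(k = k, Ct_pF = k * Cn,
               tau0_ms = fit2$tau_ms[1], tau1_ms = fit2$tau_ms[2],
               R0_MOhm = fit2$R_MOhm[1], R1_MOhm = fit2$R_MOhm[2],
               tau0_pred_ms = pred$tau_ms[1], tau1_pred_ms = pred$tau_ms[2],
               R0_pred_MOhm = pred$R_MOhm[1], R1_pred_MOhm = pred$R_MOhm[2],
               Cn_meas_pF = if (!is.null(circ)) circ$Cn_pF else NA,
               Rn_meas_MOhm = if (!is.null(circ)) circ$Rn_MOhm else NA,
               Ra_meas_MOhm = if (!is.null(circ)) circ$Ra_MOhm else NA,
               Cf_meas_pF = if (!is.null(circ)) circ$Cf_pF else NA,
               Rf_meas_MOhm = if (!is.null(circ)) circ$Rf_MOhm else NA)
  })
  res <- do.call(rbind, rows)
  rsq <- function(obs, pred) {
    if (all(is.na(obs))) return(NA_real_)
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  r2 <- c(tau0 = rsq(res$tau0_ms, res$tau0_pred_ms),
          tau1 = rsq(res$tau1_ms, res$tau1_pred_ms),
          R0 = rsq(res$R0_MOhm, res$R0_pred_MOhm),
          R1 = rsq(res$R1_MOhm, res$R1_pred_MOhm))
  list(results = res, r_squared = r2)
}

#' Saddle-node-loop sweep over specific capacitance
#'
#' Sweeps the specific membrane capacitance of the Wang-Buzsaki neuron at a
#' fixed just-supra-threshold current and locates the abrupt firing-rate jump
#' (the saddle-node-loop transition), refining the largest adjacent-point
#' frequency jump by bisection down to `resolution_uF_cm2`.
#'
#' @param Cm_range_uF_cm2 swept range of specific capacitance (uF/cm2).
#' @param coarse_step_uF_cm2 initial grid spacing (uF/cm2).
#' @param resolution_uF_cm2 bisection resolution (uF/cm2).
#' @param I_factor test current as a multiple of the rheobase (default 1.02).
#' @param rheobase_pA rheobase; estimated from a ramp when missing.
#' @param sim_ms simulated time per grid point (ms, >= 2000).
#' @param sim_dt_ms integration step (ms).
#' @param jump_ratio_min minimum adjacent-point frequency ratio accepted as a
#'   jump.
#' @param model base [wb_neuron()].
#' @return list with `critical_Cm_uF_cm2` (NA when no jump found),
#'   `jump_ratio`, `curve` (data frame `Cm_uF_cm2`, `f_Hz`), `I_pA`.
#' @export
run_snl_sweep <- function(Cm_range_uF_cm2 = c(1.2, 1.7),
                          coarse_step_uF_cm2 = 0.05,
                          resolution_uF_cm2 = 0.01,
                          I_factor = 1.02, rheobase_pA = NULL,
                          sim_ms = 3000, sim_dt_ms = 0.001,
                          jump_ratio_min = 1.5, model = wb_neuron()) {
  if (is.null(rheobase_pA)) {
    # rheobase is capacitance-independent (fixed points do not move), so one
    # accurate bisection estimate at the lower end of the sweep suffices
    m0 <- wb_neuron(Cm_uF_cm2 = Cm_range_uF_cm2[1],
                    area_um2 = model$area_um2,
                    gNa_mS_cm2 = model$gNa_mS_cm2,
                    gK_mS_cm2 = model$gK_mS_cm2,
                    gL_mS_cm2 = model$gL_mS_cm2, ENa_mV = model$ENa_mV,
                    EK_mV = model$EK_mV, EL_mV = model$EL_mV,
                    phi = model$phi)
    rheobase_pA <- rheobase_bisect(m0)
  }
  I <- I_factor * rheobase_pA
  onset <- 100
  stim <- stim_step(I, onset_ms = onset, offset_ms = onset + sim_ms)
  f_at <- function(Cm) {
    m <- wb_neuron(Cm_uF_cm2 = Cm, area_um2 = model$area_um2,
                   gNa_mS_cm2 = model$gNa_mS_cm2,
                   gK_mS_cm2 = model$gK_mS_cm2,
                   gL_mS_cm2 = model$gL_mS_cm2, ENa_mV = model$ENa_mV,
                   EK_mV = model$EK_mV, EL_mV = model$EL_mV, phi = model$phi)
    tr <- integrate_model(m, stim, onset + sim_ms, sim_dt_ms,
                          record_dt_ms = 0.05)
    firing_frequency(tr, c(onset, onset + sim_ms))
  }
  grid <- seq(Cm_range_uF_cm2[1], Cm_range_uF_cm2[2],
              by = coarse_step_uF_cm2)
  fs <- vapply(grid, f_at, numeric(1))
  curve <- data.frame(Cm_uF_cm2 = grid, f_Hz = fs)
  ratio <- function(f1, f2) {
    if (f1 <= 0 || f2 <= 0) return(Inf)
    max(f1, f2) / min(f1, f2)
  }
  ratios <- mapply(ratio, fs[-length(fs)], fs[-1])
  j <- which.max(ratios)
  if (is.finite(ratios[j]) && ratios[j] < jump_ratio_min)
    return(list(critical_Cm_uF_cm2 = NA_real_, jump_ratio = ratios[j],
                curve = curve, I_pA = I))
  lo <- grid[j]; hi <- grid[j + 1]
  f_lo <- fs[j]; f_hi <- fs[j + 1]
  while (hi - lo > resolution_uF_cm2 + 1e-12) {
    mid <- (lo + hi) / 2
    f_mid <- f_at(mid)
    curve <- rbind(curve, data.frame(Cm_uF_cm2 = mid, f_Hz = f_mid))
    if (ratio(f_lo, f_mid) >= ratio(f_mid, f_hi)) {
      hi <- mid; f_hi <- f_mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  curve <- curve[order(curve$Cm_uF_cm2), ]
  # jump size is quoted on the coarse grid; the refined bracket ratio shrinks
  # as the bracket narrows over the (finitely sharp) transition
  list(critical_Cm_uF_cm2 = (lo + hi) / 2, jump_ratio = ratios[j],
       curve = curve, I_pA = I)
}

#' Generate synthetic fixture traces
#'
#' Deterministic (seeded) synthetic stand-ins for recorded data: noisy
#' two-exponential charging responses, noisy Wang-Buzsaki spiking traces, and
#' sub-threshold pulse-train responses. Ground truth is returned alongside
#' (and written to a sidecar JSON when `out_prefix` is given).
#'
#' @param kind `"noisy-charging"`, `"noisy-spiking"` or `"pulse-train"`.
#' @param seed RNG seed (required; same seed, same output).
#' @param noise_sd_mV Gaussian voltage-noise standard deviation (mV).
#' @param out_prefix optional path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param params optional list overriding generator defaults
#'   (`noisy-charging`: `tau0_ms`, `R0_MOhm`, `tau1_ms`, `R1_MOhm`,
#'   `I_pA`, `n_pulses`; `noisy-spiking`: `C_pF`, `I_pA`, `duration_ms`;
#'   `pulse-train`: `R_MOhm`, `C_pF`, `amp_pA`, `width_ms`, `isi_ms`).
#' @return list with `trace` (a `cc_trace`), `truth` (generator parameters)
#'   and, for charging fixtures, the `protocol` stimulus.
#' @export
generate_fixtures <- function(kind = c("noisy-charging", "noisy-spiking",
                                       "pulse-train"),
                              seed, noise_sd_mV = 0.2, out_prefix = NULL,
                              params = list()) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("a seed is required for reproducible fixtures")
  set.seed(seed)
  dflt <- function(name, value)
    if (!is.null(params[[name]])) params[[name]] else value
  if (kind == "noisy-charging") {
    # defaults: the granule-cell-like reference circuit components
    tau0 <- dflt("tau0_ms", 15.1); R0 <- dflt("R0_MOhm", 119.2)
    tau1 <- dflt("tau1_ms", 0.18); R1 <- dflt("R1_MOhm", 12.3)
    n_pulses <- dflt("n_pulses", 20)
    Rdc <- R0 + R1
    I <- dflt("I_pA", -5 / Rdc * 1000)
    protocol <- build_pulse_protocol(R_estimate_MOhm = Rdc,
                                     n_pulses = n_pulses)
    I <- protocol$amplitude_pA
    dt <- 0.05
    tt <- seq(0, protocol$offset_ms + 1, by = dt)
    resp <- function(u) {
      u <- pmax(u, 0)  # response is identically 0 before the pulse edge
      I * (R0 * (1 - exp(-u / tau0)) + R1 * (1 - exp(-u / tau1))) / 1000
    }
    V <- numeric(length(tt))
    period <- protocol$width_ms + protocol$isi_ms
    for (j in seq_len(protocol$count)) {
      on_j <- protocol$onset_ms + (j - 1) * period
      V <- V + resp(tt - on_j) - resp(tt - on_j - protocol$width_ms)
    }
    V <- V + stats::rnorm(length(V), sd = noise_sd_mV)
    tr <- cc_trace(data.frame(time_ms = tt, V_mV = V,
                              Iext_pA = stim_eval(protocol, tt)), dt)
    truth <- list(kind = kind, seed = seed, tau0_ms = tau0, R0_MOhm = R0,
                  tau1_ms = tau1, R1_MOhm = R1, I_pA = I,
                  noise_sd_mV = noise_sd_mV,
                  Cn_pF = 1000 * tau0 * tau1 / (tau1 * R0 + tau0 * R1))
    out <- list(trace = tr, truth = truth, protocol = protocol)
  } else if (kind == "noisy-spiking") {
    C <- dflt("C_pF", 150); I <- dflt("I_pA", 60)
    duration <- dflt("duration_ms", 1100)
    m <- wb_with_capacitance(wb_neuron(), C)
    stim <- stim_step(I, onset_ms = 100, offset_ms = duration)
    tr <- integrate_model(m, stim, duration, 0.001, record_dt_ms = 0.05)
    tr$V_mV <- tr$V_mV + stats::rnorm(nrow(tr), sd = noise_sd_mV)
    truth <- list(kind = kind, seed = seed, C_pF = C, I_pA = I,
                  noise_sd_mV = noise_sd_mV)
    out <- list(trace = tr, truth = truth, protocol = stim)
  } else {
    R <- dflt("R_MOhm", 100); C <- dflt("C_pF", 100)
    amp <- dflt("amp_pA", 50)
    width <- dflt("width_ms", 3); isi <- dflt("isi_ms", 5)
    m <- rc_circuit(R, C)
    stim <- stim_pulse_train(amp, width, isi, count = 5, onset_ms = 50)
    dur <- stim$offset_ms + 100
    tr <- integrate_model(m, stim, dur, 0.005, record_dt_ms = 0.05)
    tr$V_mV <- tr$V_mV + stats::rnorm(nrow(tr), sd = noise_sd_mV)
    truth <- list(kind = kind, seed = seed, R_MOhm = R, C_pF = C,
                  amp_pA = amp, width_ms = width, isi_ms = isi,
                  noise_sd_mV = noise_sd_mV)
    out <- list(trace = tr, truth = truth, protocol = stim)
  }
  if (!is.null(out_prefix)) {
    write_trace(out$trace, paste0(out_prefix, ".csv"))
    jsonlite::write_json(out$truth, paste0(out_prefix, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
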