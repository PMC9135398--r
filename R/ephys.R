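#' Detect spikes in a voltage trace
#'
#' Spikes are local maxima of the membrane potential exceeding the mean
#' depolarized level during the analysis window by at least
#' `elevation_threshold_mV`, with a refractory separation of at least 1 ms.
#'
#' @param trace a `cc_trace` with a `V_mV` channel.
#' @param elevation_threshold_mV minimum elevation above the window-mean
#'   voltage (mV, default 10).
#' @param window_ms analysis interval `c(from, to)` (ms); default the full
#'   trace.
#' @param refractory_ms minimum separation between detected peaks (ms).
#' @return spike peak times (ms).
#' @export
detect_spikes <- function(trace, elevation_threshold_mV = 10,
                          window_ms = NULL, refractory_ms = 1) {
  stopifnot(inherits(trace, "cc_trace"))
  if (is.null(window_ms)) window_ms <- range(trace$time_ms)
  w <- trace_window(trace, window_ms[1], window_ms[2])
  V <- w$V_mV
  if (length(V) < 3) stop("analysis window too short")
  thr <- mean(V) + elevation_threshold_mV
  n <- length(V)
  is_peak <- c(FALSE, V[2:(n - 1)] >= V[1:(n - 2)] &
                 V[2:(n - 1)] > V[3:n], FALSE) & V > thr
  idx <- which(is_peak)
  if (!length(idx)) return(numeric(0))
  # enforce refractory separation, keeping the larger peak
  keep <- idx[1]
  for (i in idx[-1]) {
    if ((i - keep[length(keep)]) * trace_dt(w) >= refractory_ms)
      keep <- c(keep, i)
    else if (V[i] > V[keep[length(keep)]])
      keep[length(keep)] <- i
  }
  w$time_ms[keep]
}

#' Steady-state firing frequency
#'
#' Number of inter-spike intervals over the time from first to last spike,
#' computed over the final fraction of the stimulus window so that the onset
#' transient is discarded.
#'
#' @param trace a `cc_trace`.
#' @param stim_window_ms stimulus interval `c(onset, offset)` (ms).
#' @param steady_fraction final fraction of the window analyzed (default 0.8).
#' @param ... passed to [detect_spikes()].
#' @return frequency in Hz (0 with fewer than 2 spikes).
#' @export
firing_frequency <- function(trace, stim_window_ms,
                             steady_fraction = 0.8, ...) {
  from <- stim_window_ms[1] + (1 - steady_fraction) * diff(stim_window_ms)
  sp <- detect_spikes(trace, window_ms = c(from, stim_window_ms[2]), ...)
  if (length(sp) < 2) return(0)
  (length(sp) - 1) / (sp[length(sp)] - sp[1]) * 1000
}

butter_filtfilt <- function(x, fs_kHz, fc_kHz, order = 4) {
  wn <- fc_kHz / (fs_kHz / 2)
  if (wn >= 1) return(x)  # sampling too coarse to filter; use raw
  bf <- signal::butter(order, wn)
  as.numeric(signal::filtfilt(bf, x))
}

# linearly interpolated crossing time of `level` between samples i and i+1
cross_time <- function(t, y, i, level) {
  t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
}

#' Spike shape features
#'
#' Threshold is the voltage at which the derivative of the 3.3 kHz-filtered
#' trace crosses 10 mV/ms on the spike upstroke; height is peak minus
#' threshold; width is measured at half height with sub-sample interpolation.
#' The fast afterhyperpolarization (fAHP) is taken from the 1 kHz-filtered
#' trace and reported only when the dip within 10 ms after the spike is at
#' least 0.5 mV; the raw inter-spike voltage minimum and its timing are
#' reported as `AHP_mV` / `t_AHP_ms`.
#'
#' @param trace a `cc_trace` containing the spike with at least 3 ms of
#'   pre-spike context.
#' @param t_spike_ms spike peak time (ms).
#' @param t_next_spike_ms optional next spike time bounding the AHP search.
#' @param deriv_filter_kHz,fahp_filter_kHz Butterworth critical frequencies
#'   for threshold detection and fAHP extraction.
#' @param deriv_crossing_mV_ms derivative threshold (mV/ms, default 10).
#' @return an object of class `cc_spike_features`.
#' @export
spike_features <- function(trace, t_spike_ms, t_next_spike_ms = NULL,
                           deriv_filter_kHz = 3.3, fahp_filter_kHz = 1,
                           deriv_crossing_mV_ms = 10) {
  stopifnot(inherits(trace, "cc_trace"))
  dt <- trace_dt(trace)
  t <- trace$time_ms
  if (t_spike_ms - 3 < t[1] || t_spike_ms > t[length(t)])
    stop("spike not fully contained in trace (needs >= 3 ms pre-window)")
  fs_kHz <- 1 / dt

  # window: 3 ms before to 10 ms after (or to next spike)
  t_end <- min(t[length(t)], t_spike_ms + 10,
               if (!is.null(t_next_spike_ms)) t_next_spike_ms else Inf)
  w <- trace_window(trace, t_spike_ms - 3, t_end)
  tw <- w$time_ms; Vw <- w$V_mV
  ipk <- which.min(abs(tw - t_spike_ms))
  peak_mV <- Vw[ipk]
  t_peak <- tw[ipk]

  Vf <- butter_filtfilt(Vw, fs_kHz, deriv_filter_kHz)
  dV <- c(NA, diff(Vf) / dt)
  # last upward crossing of the derivative threshold before the peak
  up <- which(dV[2:ipk] >= deriv_crossing_mV_ms &
                dV[1:(ipk - 1)] < deriv_crossing_mV_ms)
  if (!length(up)) {
    thr_mV <- NA_real_; t_thr <- NA_real_
  } else {
    i <- up[length(up)]  # dV index i+1 crosses; between samples i and i+1
    t_thr <- cross_time(tw, dV[-1], i, deriv_crossing_mV_ms)
    thr_mV <- stats::approx(tw, Vf, xout = t_thr)$y
  }

  height <- peak_mV - thr_mV
  width <- NA_real_
  if (is.finite(height) && height > 0) {
    half <- thr_mV + height / 2
    iup <- which(Vw[1:(ipk - 1)] < half & Vw[2:ipk] >= half)
    idn <- which(Vw[ipk:(length(Vw) - 1)] >= half &
                   Vw[(ipk + 1):length(Vw)] < half)
    if (length(iup) && length(idn)) {
      t_up <- cross_time(tw, Vw, iup[length(iup)], half)
      j <- ipk - 1 + idn[1]
      t_dn <- cross_time(tw, Vw, j, half)
      width <- t_dn - t_up
    }
  }

  # raw inter-spike minimum (AHP)
  post <- Vw[ipk:length(Vw)]
  imin <- which.min(post)
  AHP_mV <- post[imin]
  t_AHP <- tw[ipk + imin - 1] - t_peak

  # fAHP on the 1 kHz-filtered trace within 10 ms after the peak
  Vf1 <- butter_filtfilt(Vw, fs_kHz, fahp_filter_kHz)
  post1 <- Vf1[ipk:length(Vf1)]
  fAHP_mV <- NA_real_
  if (length(post1) > 3) {
    im <- which.min(post1)
    if (im > 1 && im < length(post1)) {
      rebound <- max(post1[im:length(post1)]) - post1[im]
      if (rebound >= 0.5) fAHP_mV <- post1[im]
    }
  }

  structure(list(peak_mV = peak_mV, t_peak_ms = t_peak,
                 threshold_mV = thr_mV, t_threshold_ms = t_thr,
                 threshold_to_peak_ms = t_peak - t_thr,
                 height_mV = height, width_ms = width,
                 AHP_mV = AHP_mV, t_AHP_ms = t_AHP, fAHP_mV = fAHP_mV),
            class = "cc_spike_features")
}

#' @export
print.cc_spike_features <- function(x, ...) {
  cat(sprintf("<spike> peak %.1f mV, thr %.1f mV, h %.1f mV, w %.3g ms, AHP %.1f mV\n",
              x$peak_mV, x$threshold_mV, x$height_mV, x$width_ms, x$AHP_mV))
  invisible(x)
}

#' Mean steady-state spike features of a trace
#'
#' Detects spikes, discards those in the initial part of the pulse (varying
#' early shapes), and averages the per-spike features.
#'
#' @param trace a `cc_trace`.
#' @param stim_window_ms stimulus interval `c(onset, offset)` (ms).
#' @param discard_ms initial stretch of the pulse discarded (default 300 ms).
#' @param ... passed to [spike_features()].
#' @return list with the averaged features and the per-spike list.
#' @export
mean_spike_features <- function(trace, stim_window_ms, discard_ms = 300, ...) {
  sp <- detect_spikes(trace, window_ms = stim_window_ms)
  sp <- sp[sp >= stim_window_ms[1] + discard_ms &
             sp <= stim_window_ms[2] - 5]
  if (!length(sp)) stop("no steady-state spikes in trace")
  feats <- lapply(seq_along(sp), function(i)
    spike_features(trace, sp[i],
                   t_next_spike_ms = if (i < length(sp)) sp[i + 1] else NULL,
                   ...))
  fields <- c("peak_mV", "threshold_mV", "height_mV", "width_ms",
              "AHP_mV", "t_AHP_ms", "threshold_to_peak_ms", "fAHP_mV")
  avg <- sapply(fields, function(f) {
    vals <- vapply(feats, function(x) x[[f]], numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  })
  list(mean = as.list(avg), spikes = feats, spike_times_ms = sp)
}

#' Fit a square-root f-I curve
#'
#' Least squares of `f(I) = gain * sqrt(I - Irheo)` for `I > Irheo` (and
#' `f = 0` below). Zero-frequency points constrain the rheobase from below;
#' the gain is profiled in closed form and the rheobase found by 1-D
#' optimization.
#'
#' @param I_pA,f_Hz currents and measured firing frequencies (>= 4 points,
#'   >= 2 non-zero frequencies).
#' @param tol_Hz tolerance for the monotonicity check (Hz).
#' @return object of class `cc_fi_fit`: list with `gain`, `Irheo_pA`,
#'   `residuals`, `points`, `monotone`.
#' @export
fit_fi <- function(I_pA, f_Hz, tol_Hz = 0.5) {
  stopifnot(length(I_pA) == length(f_Hz))
  ord <- order(I_pA)
  I <- I_pA[ord]; f <- f_Hz[ord]
  if (length(I) < 4 || sum(f > 0) < 2)
    stop("need >= 4 points with >= 2 non-zero frequencies")
  monotone <- all(diff(f) >= -tol_Hz)
  if (!monotone) stop("non-monotonically increasing f-I curve; excluded")
  lo <- if (any(f == 0)) max(I[f == 0]) else min(I) - diff(range(I))
  hi <- min(I[f > 0])
  if (lo >= hi) lo <- hi - diff(range(I))
  sse <- function(Irheo) {
    x <- sqrt(pmax(I - Irheo, 0))
    g <- sum(f * x) / sum(x^2)
    sum((f - g * x)^2)
  }
  opt <- stats::optimize(sse, c(lo, hi - 1e-9))
  Irheo <- opt$minimum
  x <- sqrt(pmax(I - Irheo, 0))
  gain <- sum(f * x) / sum(x^2)
  if (!is.finite(gain) || gain <= 0) stop("degenerate f-I fit")
  structure(list(gain = gain, Irheo_pA = Irheo,
                 residuals = f - gain * x,
                 points = data.frame(I_pA = I, f_Hz = f),
                 monotone = monotone),
            class = "cc_fi_fit")
}

#' @export
print.cc_fi_fit <- function(x, ...) {
  cat(sprintf("<f-I fit> f = %.3g * sqrt(I - %.4g pA) Hz\n",
              x$gain, x$Irheo_pA))
  invisible(x)
}

#' Analytic capacitance scaling of the f-I gain
#'
#' For a neuron with square-root (class 1) f-I curve the gain scales as
#' `gain(C) = gain(Cc) * Cc / C` with a constant rheobase; the linearized
#' gain reduction per unit capacitance is `-gain(Cc)/Cc`.
#'
#' @param gain_at_Cc measured gain at the original capacitance.
#' @param Cc_pF original capacitance (pF).
#' @param C_pF capacitance at which to predict the gain (pF).
#' @return list with `gain_predicted`, `dgain_per_pF` and
#'   `dgain_per_10pF`.
#' @export
gain_capacitance_prediction <- function(gain_at_Cc, Cc_pF, C_pF) {
  stopifnot(gain_at_Cc > 0, Cc_pF > 0, all(C_pF > 0))
  list(gain_predicted = gain_at_Cc * Cc_pF / C_pF,
       dgain_per_pF = -gain_at_Cc / Cc_pF,
       dgain_per_10pF = -10 * gain_at_Cc / Cc_pF)
}

#' Hypothetical rescaled spike
#'
#' The spike shape expected if the membrane currents were unchanged while the
#' capacitance changed from `Cc` to `Ct`:
#' `V_hypo(t) = V(t0) + (Cc/Ct) * (V(t) - V(t0))` with the reference point
#' `t0 = t_spike - 3 ms`, shortly before onset of the spike-generating
#' currents.
#'
#' @param spike_trace a `cc_trace` covering `[t_spike - 3 ms, spike end]`.
#' @param Cc_pF,Ct_pF original and hypothetical capacitance (pF).
#' @param t_spike_ms spike peak time (ms).
#' @return a `cc_trace` with the rescaled `V_mV`.
#' @export
hypothetical_spike <- function(spike_trace, Cc_pF, Ct_pF, t_spike_ms) {
  stopifnot(inherits(spike_trace, "cc_trace"), Cc_pF > 0, Ct_pF > 0)
  t0 <- t_spike_ms - 3
  if (t0 < spike_trace$time_ms[1])
    stop("insufficient pre-spike window (need 3 ms before the peak)")
  V0 <- stats::approx(spike_trace$time_ms, spike_trace$V_mV, xout = t0)$y
  out <- as.data.frame(spike_trace)
  out$V_mV <- V0 + Cc_pF / Ct_pF * (out$V_mV - V0)
  cc_trace(out, trace_dt(spike_trace))
}

#' Charge metrics of a spike
#'
#' Depolarizing charge `Q+ = C * dV_AP` and sodium charge
#' `QNa = integral |I_Na| dt` over the spike window (from threshold crossing
#' to return to the threshold voltage, or at most `max_window_ms` after it).
#'
#' @param trace a `cc_trace`; `QNa` requires an `INa_pA` channel.
#' @param C_pF capacitance the spike was recorded at (pF).
#' @param t_spike_ms spike peak time (ms).
#' @param deltaV_mode `"threshold-to-peak"` (default) or `"ahp-to-peak"`.
#' @param max_window_ms upper bound of the integration window after threshold
#'   crossing (ms).
#' @return object of class `cc_charge_metrics`: `Qplus_pC`, `QNa_pC` (NA if
#'   no sodium channel recorded), `C_pF`, `deltaV_AP_mV`, window bounds.
#' @export
charge_metrics <- function(trace, C_pF, t_spike_ms,
                           deltaV_mode = c("threshold-to-peak", "ahp-to-peak"),
                           max_window_ms = 8) {
  deltaV_mode <- match.arg(deltaV_mode)
  stopifnot(C_pF > 0)
  ft <- spike_features(trace, t_spike_ms)
  if (!is.finite(ft$threshold_mV))
    stop("no threshold crossing found for spike at ", t_spike_ms, " ms")
  deltaV <- switch(deltaV_mode,
                   "threshold-to-peak" = ft$height_mV,
                   "ahp-to-peak" = ft$peak_mV - ft$AHP_mV)
  # spike window: threshold crossing to return to threshold voltage
  t0 <- ft$t_threshold_ms
  w <- trace_window(trace, t0, t0 + max_window_ms)
  below <- which(w$time_ms > ft$t_peak_ms & w$V_mV <= ft$threshold_mV)
  t1 <- if (length(below)) w$time_ms[below[1]] else t0 + max_window_ms
  QNa <- NA_real_
  if ("INa_pA" %in% names(trace)) {
    wi <- trace_window(trace, t0, t1)
    QNa <- sum(abs(wi$INa_pA)) * trace_dt(trace) / 1000  # pA*ms -> pC
  }
  structure(list(Qplus_pC = C_pF * deltaV / 1000, QNa_pC = QNa,
                 C_pF = C_pF, deltaV_AP_mV = deltaV,
                 window_ms = c(t0, t1)),
            class = "cc_charge_metrics")
}

#' Temporal-integration ratio of a pulse-train response
#'
#' Ratio of the peak deflection after the fifth pulse to that after the first
#' pulse, baselined at the pre-train resting level; defined for sub-threshold
#' responses only.
#'
#' @param trace a `cc_trace` of the response.
#' @param stimulus the pulse-train `cc_stimulus` (>= 5 pulses).
#' @return dimensionless ratio.
#' @export
integration_ratio <- function(trace, stimulus) {
  stopifnot(inherits(stimulus, "cc_stimulus"), stimulus$kind == "pulse_train",
            stimulus$count >= 5)
  baseline_w <- trace_window(trace, max(0, stimulus$onset_ms - 20),
                             stimulus$onset_ms)
  base <- mean(baseline_w$V_mV)
  if (length(detect_spikes(trace, elevation_threshold_mV = 30)))
    stop("spikes detected during the train; integration ratio is a ",
         "sub-threshold measure")
  period <- stimulus$width_ms + stimulus$isi_ms
  peak_after <- function(j) {
    from <- stimulus$onset_ms + (j - 1) * period
    w <- trace_window(trace, from, from + period)
    dev <- w$V_mV - base
    dev[which.max(abs(dev))]
  }
  peak_after(5) / peak_after(1)
}

#' Impedance of a capacitance-clamped RC circuit
#'
#' Closed-loop impedance amplitude of an RC circuit under the discrete-time
#' clamp controller with zero-order hold, derived from the z-transform of the
#' exactly discretized RC update, compared with the ideal target RC
#' `|Z| = R / sqrt(1 + (2 pi f R Ct)^2)`.
#'
#' @param R_MOhm,Cc_pF circuit resistance and capacitance.
#' @param Ct_pF clamp target capacitance.
#' @param f_dyn_kHz clamp update frequency (kHz).
#' @param frequencies_Hz frequencies to evaluate (must be below the Nyquist
#'   frequency `f_dyn/2`).
#' @param delay_mode `"zero-delay"` or `"one-cycle"`.
#' @return data frame with `freq_Hz`, `Z_clamped_MOhm`, `Z_target_MOhm`,
#'   `Z_cell_MOhm` (unclamped discrete RC, for reference).
#' @export
clamped_rc_impedance <- function(R_MOhm, Cc_pF, Ct_pF, f_dyn_kHz,
                                 frequencies_Hz,
                                 delay_mode = c("zero-delay", "one-cycle")) {
  delay_mode <- match.arg(delay_mode)
  nyq_Hz <- f_dyn_kHz * 1000 / 2
  if (any(frequencies_Hz >= nyq_Hz))
    stop("frequencies must be below the Nyquist frequency ", nyq_Hz, " Hz")
  dt <- 1 / f_dyn_kHz                      # ms
  tau <- R_MOhm * Cc_pF / 1000             # ms
  a <- exp(-dt / tau)
  r <- R_MOhm / 1000                       # mV/pA
  beta <- (Cc_pF - Ct_pF) / Ct_pF
  zZ <- function(beta_loc) {
    vapply(frequencies_Hz, function(f) {
      z <- exp(1i * 2 * pi * f * dt / 1000)
      ctrl_den <- if (delay_mode == "one-cycle") 1 + beta_loc / z^2
                  else 1 + beta_loc / z
      H <- beta_loc * Cc_pF * (1 - 1 / z) / (dt * ctrl_den)
      Z <- (1 - a) * r / (z - a - (1 - a) * r * H)
      abs(Z) * 1000                        # MOhm
    }, numeric(1))
  }
  Zc <- zZ(beta)
  Z0 <- zZ(0)
  Zt <- R_MOhm / sqrt(1 + (2 * pi * frequencies_Hz * R_MOhm * Ct_pF * 1e-6)^2)
  data.frame(freq_Hz = frequencies_Hz, Z_clamped_MOhm = Zc,
             Z_target_MOhm = Zt, Z_cell_MOhm = Z0)
}

#' Measure impedance amplitude by sinusoidal driving
#'
#' Drives a (possibly clamped) model with a sinusoidal current and extracts
#' the voltage amplitude at the driving frequency by least-squares projection
#' on sine/cosine regressors, discarding the initial transient.
#'
#' @param model a passive cell model.
#' @param freq_Hz driving frequency (Hz).
#' @param clamp optional [clamp_config()].
#' @param amplitude_pA driving amplitude (pA).
#' @param n_cycles number of cycles simulated (the first 20\% discarded).
#' @param sim_dt_ms integration step (ms).
#' @return impedance amplitude in MOhm.
#' @export
measure_impedance <- function(model, freq_Hz, clamp = NULL,
                              amplitude_pA = 20, n_cycles = 20,
                              sim_dt_ms = 0.001) {
  period <- 1000 / freq_Hz
  dur <- n_cycles * period
  if (is.null(clamp)) {
    stim <- stim_sinusoid(amplitude_pA, freq_Hz)
    tr <- integrate_model(model, stim, dur, sim_dt_ms, record_dt_ms = sim_dt_ms)
  } else {
    # deliver the stimulus sampled and held at the clamp interval, as a
    # dynamic-clamp DAC would
    ts <- seq(0, dur, by = clamp$dt_ms)
    stim <- stim_samples(amplitude_pA * sin(2 * pi * freq_Hz * ts / 1000),
                         sample_dt_ms = clamp$dt_ms)
    # record at the clamp sampling instants: the amplitude of the sampled
    # voltage sequence is what the discrete transfer function describes
    tr <- run_clamped(model, clamp, stim, dur, sim_dt_ms,
                      record_dt_ms = clamp$dt_ms)
  }
  w <- trace_window(tr, 0.2 * dur, dur)
  om <- 2 * pi * freq_Hz / 1000
  X <- cbind(sin(om * w$time_ms), cos(om * w$time_ms))
  cf <- stats::lm.fit(X, w$V_mV - mean(w$V_mV))$coefficients
  sqrt(sum(cf^2)) / amplitude_pA * 1000   # mV/pA -> MOhm
}
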