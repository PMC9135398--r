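#' Pulse protocol for capacitance measurement
#'
#' Twenty hyperpolarizing pulses of 200 ms with 400 ms pauses, with the
#' amplitude chosen to produce a small target deflection (default -5 mV) so
#' that active currents interfere as little as possible.
#'
#' @param target_deflection_mV desired steady-state deflection (mV).
#' @param R_estimate_MOhm rough input-resistance estimate used to size the
#'   pulse amplitude (MOhm).
#' @param n_pulses,width_ms,pause_ms protocol geometry.
#' @param onset_ms time of the first pulse (ms).
#' @return a pulse-train `cc_stimulus`.
#' @export
build_pulse_protocol <- function(target_deflection_mV = -5, R_estimate_MOhm,
                                 n_pulses = 20, width_ms = 200,
                                 pause_ms = 400, onset_ms = 100) {
  if (!(R_estimate_MOhm > 0)) stop("resistance estimate must be positive")
  amp_pA <- target_deflection_mV / R_estimate_MOhm * 1000
  stim_pulse_train(amplitude_pA = amp_pA, width_ms = width_ms,
                   isi_ms = pause_ms, count = n_pulses, onset_ms = onset_ms)
}

#' Average the pulse responses of a trace
#'
#' Cuts the response to every pulse of the protocol, baseline-subtracts,
#' averages across repetitions and returns the mean charging curve. With
#' `segment = "offset"` (default) the artifact-free recharging at the pulse
#' end is used, reflected about the steady deflection level so that it
#' follows the same charging convention `V(t) = sum v_i (1 - exp(-t/tau_i))`
#' as the onset segment.
#'
#' @param trace a `cc_trace` covering all pulses.
#' @param protocol the pulse-train `cc_stimulus` that produced the trace.
#' @param segment `"offset"` or `"onset"`.
#' @return a `cc_trace` with `time_ms` starting at 0 (the pulse edge) and the
#'   baseline-subtracted mean response in `V_mV`; attribute `n_averaged`.
#' @export
average_pulse_response <- function(trace, protocol,
                                   segment = c("offset", "onset")) {
  segment <- match.arg(segment)
  stopifnot(inherits(trace, "cc_trace"), inherits(protocol, "cc_stimulus"),
            protocol$kind == "pulse_train")
  dt <- trace_dt(trace)
  width <- protocol$width_ms
  pause <- protocol$isi_ms
  period <- width + pause
  t_end <- max(trace$time_ms)
  n_complete <- 0
  for (j in seq_len(protocol$count))
    if (protocol$onset_ms + j * period <= t_end + dt / 2)
      n_complete <- n_complete + 1
  if (n_complete < 2) stop("need at least 2 complete pulses, have ", n_complete)

  n_seg <- floor((if (segment == "onset") width else pause) / dt)
  acc <- numeric(n_seg)
  for (j in seq_len(n_complete)) {
    onset_j <- protocol$onset_ms + (j - 1) * period
    edge <- if (segment == "onset") onset_j else onset_j + width
    i0 <- round(edge / dt)  # sample index of pulse edge (time = i*dt)
    seg <- trace$V_mV[(i0 + 1):(i0 + n_seg)]
    if (segment == "onset") {
      # baseline: late pre-onset (end of previous recharge)
      bl_idx <- round((edge - 0.25 * pause) / dt):i0
      base <- mean(trace$V_mV[pmax(bl_idx, 1) + 1])
      acc <- acc + (seg - base)
    } else {
      # deflection level: late in-pulse plateau; reflect about it
      pl_idx <- round((edge - 0.25 * width) / dt):i0
      plateau <- mean(trace$V_mV[pl_idx + 1])
      acc <- acc + (plateau - seg)
    }
  }
  # no single-sample re-zeroing: the averaged baselines above already put the
  # pulse edge at zero in expectation, and subtracting one noisy sample would
  # introduce a correlated offset that biases nested-fit comparisons
  mean_v <- acc / n_complete
  out <- cc_trace(data.frame(time_ms = (seq_len(n_seg)) * dt - dt,
                             V_mV = mean_v), dt)
  attr(out, "n_averaged") <- n_complete
  out
}

#' Fit a sum of exponentials to a charging curve
#'
#' Least-squares fit of `V(t) = sum_{i} v_i (1 - exp(-t/tau_i))` with 1-3
#' components by Levenberg-Marquardt, initialized by peeling (slow tail
#' first, then the residual). Components are returned in descending-tau
#' order with resistance amplitudes `R_i = v_i / I_ext`.
#'
#' @param mean_trace baseline-subtracted charging curve starting at the pulse
#'   edge (a `cc_trace` as from [average_pulse_response()]).
#' @param I_ext_pA stimulus amplitude that produced the curve (pA, non-zero).
#' @param n_components 1, 2 or 3.
#' @param window_ms optional fit window; default from the pulse edge to five
#'   times a rough single-exponential time-constant estimate.
#' @return an object of class `cc_exp_components`: list with `n`, `tau_ms`,
#'   `R_MOhm`, `v_mV`, `I_ext_pA`, `rss`, `n_samples`, `ill_separated`.
#' @export
fit_exponentials <- function(mean_trace, I_ext_pA, n_components,
                             window_ms = NULL) {
  stopifnot(inherits(mean_trace, "cc_trace"), n_components %in% 1:3)
  if (I_ext_pA == 0) stop("stimulus amplitude must be non-zero")
  t <- mean_trace$time_ms
  v <- mean_trace$V_mV

  # rough single-exponential scale for the fit window
  vss_rough <- mean(v[t >= stats::quantile(t, 0.9)])
  tau_rough <- tryCatch({
    i63 <- which(abs(v) >= abs(vss_rough) * (1 - exp(-1)))[1]
    max(t[i63], 5 * trace_dt(mean_trace))
  }, error = function(e) max(t) / 5)
  if (is.null(window_ms)) window_ms <- min(max(t), 5 * tau_rough)
  keep <- t <= window_ms
  t <- t[keep]; v <- v[keep]
  n_samples <- length(t)

  model_fun <- function(p, t) {
    n <- length(p) / 2
    out <- numeric(length(t))
    for (i in seq_len(n))
      out <- out + p[n + i] * (1 - exp(-t / p[i]))
    out
  }

  # peeling initialization
  vss <- mean(v[t >= 0.8 * max(t)])
  init_taus <- tau_rough * c(1, 0.05, 0.005)[seq_len(n_components)]
  init_vs <- vss * c(0.9, 0.1, 0.02)[seq_len(n_components)]
  if (n_components >= 2) {
    tail_idx <- t > 3 * init_taus[2]
    if (sum(tail_idx) > 10) {
      slow <- tryCatch(
        minpack.lm::nlsLM(y ~ a * (1 - exp(-x / tau)),
                          data = data.frame(x = t[tail_idx], y = v[tail_idx]),
                          start = list(a = vss, tau = tau_rough),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(slow)) {
        cf <- stats::coef(slow)
        init_taus[1] <- abs(cf[["tau"]]); init_vs[1] <- cf[["a"]]
        resid_early <- v - cf[["a"]] * (1 - exp(-t / abs(cf[["tau"]])))
        init_vs[2] <- mean(resid_early[t >= 0.5 * init_taus[2] &
                                         t <= 5 * init_taus[2]])
        if (!is.finite(init_vs[2]) || init_vs[2] == 0)
          init_vs[2] <- 0.1 * vss
      }
    }
  }

  resid_fun <- function(p) model_fun(p, t) - v
  fit <- minpack.lm::nls.lm(
    par = c(init_taus, init_vs), fn = resid_fun,
    lower = c(rep(trace_dt(mean_trace) / 10, n_components),
              rep(-Inf, n_components)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (fit$info == 0)
    stop("exponential fit failed to converge (init taus: ",
         paste(signif(init_taus, 3), collapse = ", "), ")")
  p <- fit$par
  taus <- p[seq_len(n_components)]
  vs <- p[n_components + seq_len(n_components)]
  if (any(taus <= 0)) stop("fit produced a non-positive time constant")
  ord <- order(taus, decreasing = TRUE)
  taus <- taus[ord]; vs <- vs[ord]
  rss <- sum(resid_fun(p)^2)
  ill <- n_components >= 2 && taus[1] / taus[2] < 3
  structure(list(n = n_components, tau_ms = taus,
                 R_MOhm = 1000 * vs / I_ext_pA,   # mV/pA = GOhm -> MOhm
                 v_mV = vs, I_ext_pA = I_ext_pA, rss = rss,
                 n_samples = n_samples, ill_separated = ill),
            class = "cc_exp_components")
}

#' @export
print.cc_exp_components <- function(x, ...) {
  cat("<exponential fit>", x$n, "component(s)\n")
  for (i in seq_len(x$n))
    cat(sprintf("  tau%d = %.4g ms, R%d = %.4g MOhm\n",
                i - 1, x$tau_ms[i], i - 1, x$R_MOhm[i]))
  cat("  RSS =", format(x$rss), "on", x$n_samples, "samples\n")
  invisible(x)
}

#' Compare nested exponential fits by F-test
#'
#' `F = ((RSS_a - RSS_b)/(p_b - p_a)) / (RSS_b/(N - p_b))` with `p = 2n`
#' parameters per fit; the larger model is selected iff `p < alpha`.
#'
#' @param fit_a,fit_b `cc_exp_components` of the same data, `fit_a` nested in
#'   (fewer components than) `fit_b`.
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `p_value`, `selected_n`.
#' @export
compare_fits <- function(fit_a, fit_b, alpha = 0.05) {
  stopifnot(inherits(fit_a, "cc_exp_components"),
            inherits(fit_b, "cc_exp_components"))
  if (fit_a$n >= fit_b$n) stop("fit_a must have fewer components than fit_b")
  if (fit_a$n_samples != fit_b$n_samples)
    stop("fits must be of the same data (sample counts differ)")
  p_a <- 2 * fit_a$n; p_b <- 2 * fit_b$n
  N <- fit_b$n_samples
  denom <- fit_b$rss / (N - p_b)
  if (!is.finite(denom) || denom <= 0)
    stop("degenerate fit comparison (zero residual in the larger model)")
  Fstat <- ((fit_a$rss - fit_b$rss) / (p_b - p_a)) / denom
  if (!is.finite(Fstat)) stop("degenerate fit comparison (identical fits)")
  Fstat <- max(Fstat, 0)
  p_value <- stats::pf(Fstat, p_b - p_a, N - p_b, lower.tail = FALSE)
  list(F = Fstat, p_value = p_value,
       selected_n = if (p_value < alpha) fit_b$n else fit_a$n)
}

#' Total capacitance of an iso-potential cell from its charging curve
#'
#' `C = tau0 / R0`, the slowest time constant over its resistance amplitude.
#'
#' @param tau0_ms slowest time constant (ms).
#' @param R0_MOhm its resistance amplitude (MOhm).
#' @return capacitance in pF.
#' @export
capacitance_isopotential <- function(tau0_ms, R0_MOhm) {
  stopifnot(tau0_ms > 0, R0_MOhm > 0)
  1000 * tau0_ms / R0_MOhm
}

#' Predicted charging-curve components of a two-compartment circuit
#'
#' Analytic forward map: eigenvalues of the 2x2 circuit give the time
#' constants, the eigenvector projection of the somatic step response gives
#' the amplitudes. Substituting `Cn -> Ct` while holding the other circuit
#' parameters fixed predicts the observables of a clamped cell.
#'
#' @param circ a [two_compartment()] model.
#' @return a `cc_exp_components` with `n = 2` (per unit stimulus current,
#'   `I_ext_pA = 1`).
#' @export
components_from_circuit <- function(circ) {
  stopifnot(inherits(circ, "cc_two_compartment"))
  gn <- 1000 / circ$Rn_MOhm; ga <- 1000 / circ$Ra_MOhm
  gf <- 1000 / circ$Rf_MOhm                      # nS
  Cn <- circ$Cn_pF; Cf <- circ$Cf_pF
  A <- matrix(c(-(gn + ga) / Cn, ga / Cf,
                ga / Cn, -(gf + ga) / Cf), 2, 2)
  eg <- eigen(A)
  lam <- eg$values
  if (any(Im(lam) != 0) || abs(lam[1] - lam[2]) < 1e-12 * abs(lam[1]))
    stop("degenerate circuit: eigenvalue time constants coincide")
  lam <- Re(lam); U <- Re(eg$vectors)
  I <- 1  # pA; amplitudes scale linearly
  b <- c(I / Cn, 0)
  xss <- -solve(A, b)
  w <- solve(U, -xss)
  v <- -w * U[1, ]                 # somatic amplitude of each mode
  tau <- -1 / lam
  ord <- order(tau, decreasing = TRUE)
  structure(list(n = 2L, tau_ms = tau[ord],
                 R_MOhm = 1000 * v[ord] / I,      # mV/pA = GOhm -> MOhm
                 v_mV = v[ord], I_ext_pA = I, rss = 0,
                 n_samples = NA_integer_, ill_separated = FALSE),
            class = "cc_exp_components")
}

#' Near capacitance from two charging-curve components
#'
#' Closed form `Cn = tau0*tau1 / (tau1*R0 + tau0*R1)`, which follows from the
#' initial charging slope `dV/dt(0+) = I/Cn` and therefore holds for any
#' clamping factor. In the fast-limit `tau1, R1 -> 0` with `R1 << tau1` it
#' reduces to the isopotential `tau0/R0`.
#'
#' @param tau0_ms,R0_MOhm slow component.
#' @param tau1_ms,R1_MOhm fast component.
#' @return near capacitance in pF.
#' @export
near_capacitance_from_components <- function(tau0_ms, R0_MOhm,
                                             tau1_ms, R1_MOhm) {
  stopifnot(tau0_ms > 0, tau1_ms > 0, R0_MOhm > 0, R1_MOhm > 0)
  1000 * tau0_ms * tau1_ms / (tau1_ms * R0_MOhm + tau0_ms * R1_MOhm)
}

#' Two-compartment circuit from charging-curve components
#'
#' Inverse of [components_from_circuit()]. The near capacitance follows in
#' closed form from the initial slope of the charging curve,
#' `Cn = tau0*tau1 / (tau1*R0 + tau0*R1)`; the remaining parameters
#' `(Rn, Ra, Cf, Rf)` are obtained by solving the observable equations under
#' the (k-adjusted) uniform-time-constant constraint `Rn*Cn = k*Rf*Cf`, and
#' the solution is validated by a round trip through the forward map.
#'
#' @param comp a `cc_exp_components` with `n = 2`.
#' @param k clamping factor of the constraint (1 for an unclamped cell).
#' @param tol relative round-trip residual accepted for the solution.
#' @return a [two_compartment()] model carrying `k`.
#' @export
circuit_from_components <- function(comp, k = 1, tol = 1e-6) {
  stopifnot(inherits(comp, "cc_exp_components"), comp$n == 2, k > 0)
  tau0 <- comp$tau_ms[1]; tau1 <- comp$tau_ms[2]
  R0 <- comp$R_MOhm[1]; R1 <- comp$R_MOhm[2]
  if (!(tau0 > tau1) || tau1 <= 0 || R0 <= 0 || R1 <= 0)
    stop("components must satisfy tau0 > tau1 > 0 and R0, R1 > 0")
  Cn <- near_capacitance_from_components(tau0, R0, tau1, R1)

  obs <- log(c(tau0, tau1, R0, R1))
  resid <- function(lp) {
    Rn <- exp(lp[1]); Ra <- exp(lp[2]); Rf <- exp(lp[3])
    Cf <- Rn * Cn / (k * Rf)
    pred <- tryCatch(components_from_circuit(
      two_compartment(Cn, Rn, Ra, Cf, Rf, k = k)),
      error = function(e) NULL)
    if (is.null(pred) || any(pred$tau_ms <= 0) || any(pred$R_MOhm <= 0))
      return(rep(1e3, 4))
    log(c(pred$tau_ms, pred$R_MOhm)) - obs
  }
  # initialization: tau0 ~ Rn*Cn, DC resistance and total capacitance
  Rn0 <- 1000 * tau0 / Cn
  Rdc <- R0 + R1
  Cf0 <- 1000 * tau0 / Rdc
  Rf0 <- Rn0 * Cn / (k * Cf0)
  Rp <- if (Rn0 > Rdc * 1.001) Rn0 * Rdc / (Rn0 - Rdc) else 2 * Rdc
  Ra0 <- max(Rp - Rf0, 0.01 * Rdc)
  fit <- minpack.lm::nls.lm(par = log(c(Rn0, Ra0, Rf0)), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  rel <- sqrt(mean(resid(fit$par)^2))
  if (!is.finite(rel) || rel > tol)
    stop("no positive-parameter circuit reproduces the components ",
         "(round-trip residual ", format(rel), ")")
  Rn <- exp(fit$par[1]); Ra <- exp(fit$par[2]); Rf <- exp(fit$par[3])
  Cf <- Rn * Cn / (k * Rf)
  two_compartment(Cn, Rn, Ra, Cf, Rf, k = k)
}

#' Corrected target capacitance
#'
#' When the capacitance used online to run the clamp (`Cc_online`) differs
#' from a more accurate offline estimate (`Cc_offline`), the effectively
#' targeted capacitance preserves the targeted change:
#' `Ct_corr = Cc_off + (Ct_on - Cc_on)`, with the mapping factor
#' `k = Ct_corr / Cc_off`.
#'
#' @param Cc_offline_pF,Cc_online_pF offline and online estimates of the cell
#'   capacitance (pF).
#' @param Ct_online_pF target capacitance used online (pF).
#' @return list with `Ct_corrected_pF` and `k`.
#' @export
corrected_target <- function(Cc_offline_pF, Cc_online_pF, Ct_online_pF) {
  stopifnot(Cc_offline_pF > 0, Cc_online_pF > 0, Ct_online_pF > 0)
  Ct_corr <- Cc_offline_pF + (Ct_online_pF - Cc_online_pF)
  if (Ct_corr <= 0) stop("corrected target capacitance is non-positive")
  list(Ct_corrected_pF = Ct_corr, k = Ct_corr / Cc_offline_pF)
}

#' Full capacitance-measurement protocol
#'
#' Runs (or consumes) the pulse protocol, averages the responses, fits 1-3
#' exponential components, selects the component count by F-test, and maps a
#' two-component fit onto the two-compartment circuit.
#'
#' @param x a cell model (the protocol is simulated, optionally clamped) or a
#'   recorded pulse-protocol `cc_trace`.
#' @param clamp optional [clamp_config()]; when given, the simulated cell is
#'   clamped during the measurement and the mapping uses
#'   `k = Ct / electrode_capacitance(model)`.
#' @param protocol the pulse protocol; defaults to [build_pulse_protocol()]
#'   sized by the model's DC input resistance (required for trace input).
#' @param segment charging segment to fit, `"offset"` (default) or `"onset"`.
#' @param sim_dt_ms integration step for simulated protocols (ms).
#' @param record_dt_ms sampling interval of the analyzed trace (ms); default
#'   0.05 ms, the 20 kHz acquisition interval.
#' @param n_max largest component count fitted (1-3).
#' @param alpha F-test significance level.
#' @param k mapping factor override; default from `clamp` (or 1).
#' @return list with the averaged curve, `fits` (per component count),
#'   `comparisons`, `selected_n`, `C_total_pF` (tau0/R0), and for a selected
#'   two-component fit the mapped `circuit` and `Cn_pF`.
#' @export
measure_capacitance <- function(x, clamp = NULL, protocol = NULL,
                                segment = c("offset", "onset"),
                                sim_dt_ms = 0.005, record_dt_ms = 0.05,
                                n_max = 3, alpha = 0.05, k = NULL) {
  segment <- match.arg(segment)
  if (inherits(x, "cc_model")) {
    if (is.null(protocol))
      protocol <- build_pulse_protocol(R_estimate_MOhm = dc_input_resistance(x))
    duration <- protocol$offset_ms + 1
    trace <- if (is.null(clamp))
      integrate_model(x, protocol, duration, sim_dt_ms,
                      record_dt_ms = record_dt_ms)
    else
      run_clamped(x, clamp, protocol, duration, sim_dt_ms,
                  record_dt_ms = record_dt_ms)
    if (is.null(k))
      k <- if (is.null(clamp)) 1 else clamp$Ct_pF / electrode_capacitance(x)
  } else if (inherits(x, "cc_trace")) {
    if (is.null(protocol))
      stop("trace input requires the pulse protocol that produced it")
    trace <- x
    if (is.null(k)) k <- 1
  } else stop("x must be a cell model or a trace")

  mean_trace <- average_pulse_response(trace, protocol, segment)
  I_ext <- protocol$amplitude_pA
  fits <- lapply(seq_len(n_max), function(n)
    tryCatch(fit_exponentials(mean_trace, I_ext, n), error = function(e) NULL))
  if (is.null(fits[[1]])) stop("single-exponential fit failed")
  selected <- 1L
  comparisons <- list()
  for (n in seq_len(n_max - 1)) {
    if (is.null(fits[[n + 1]])) break
    cmp <- tryCatch(compare_fits(fits[[selected]], fits[[n + 1]], alpha),
                    error = function(e) NULL)
    if (is.null(cmp)) break
    comparisons[[length(comparisons) + 1]] <- cmp
    if (cmp$selected_n > selected) selected <- as.integer(cmp$selected_n)
    else break
  }
  best <- fits[[selected]]
  out <- list(mean_trace = mean_trace, fits = fits,
              comparisons = comparisons, selected_n = selected,
              C_total_pF = capacitance_isopotential(best$tau_ms[1],
                                                    best$R_MOhm[1]),
              k = k)
  # the circuit mapping always uses the two-component fit (higher component
  # counts serve model selection only)
  if (!is.null(fits[[2]])) {
    circ <- tryCatch(circuit_from_components(fits[[2]], k = k),
                     error = function(e) NULL)
    out$circuit <- circ
    out$Cn_pF <- if (!is.null(circ)) circ$Cn_pF else NA_real_
  }
  out
}
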