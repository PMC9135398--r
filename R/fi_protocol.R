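#' Rheobase estimate from a current ramp
#'
#' Injects a slow ramp (default 5 s to 250 pA) and reports the current at the
#' first spike.
#'
#' @param model a cell model.
#' @param clamp optional [clamp_config()].
#' @param height_pA,duration_ms ramp parameters.
#' @param sim_dt_ms integration step (ms).
#' @return estimated rheobase (pA).
#' @export
rheobase_from_ramp <- function(model, clamp = NULL, height_pA = 250,
                               duration_ms = 5000, sim_dt_ms = 0.005) {
  stim <- stim_ramp(height_pA, duration_ms, onset_ms = 0)
  tr <- if (is.null(clamp))
    integrate_model(model, stim, duration_ms, sim_dt_ms, record_dt_ms = 0.05)
  else run_clamped(model, clamp, stim, duration_ms, sim_dt_ms,
                   record_dt_ms = 0.05)
  # ramp responses are not stationary; detect upward crossings of a fixed
  # elevation over the resting level instead of the window mean
  V0 <- tr$V_mV[1]
  above <- tr$V_mV > V0 + 40
  if (!any(above)) stop("no spike during the ramp; increase the ramp height")
  t_first <- tr$time_ms[which(above)[1]]
  stim_eval(stim, t_first)
}

#' Rheobase by bisection on step responses
#'
#' Brackets the minimal step current that elicits repetitive firing (at least
#' two spikes in the second half of a long step). Slower than the ramp
#' estimate but free of the ramp's bifurcation delay, which matters when a
#' current truly close to threshold is needed.
#'
#' @param model a cell model.
#' @param lo_pA,hi_pA initial bracket (pA); `hi_pA` must elicit firing.
#' @param tol_pA bracket width at which to stop (pA).
#' @param step_ms step duration per probe (ms).
#' @param sim_dt_ms integration step (ms).
#' @return rheobase estimate (pA).
#' @export
rheobase_bisect <- function(model, lo_pA = 0, hi_pA = 100, tol_pA = 0.1,
                            step_ms = 2000, sim_dt_ms = 0.002) {
  fires <- function(I) {
    tr <- integrate_model(model, stim_step(I, 50, 50 + step_ms),
                          50 + step_ms, sim_dt_ms, record_dt_ms = 0.05)
    length(detect_spikes(tr, window_ms = c(50 + step_ms / 2,
                                           50 + step_ms))) >= 2
  }
  if (!fires(hi_pA)) stop("upper bracket does not elicit firing")
  while (hi_pA - lo_pA > tol_pA) {
    mid <- (lo_pA + hi_pA) / 2
    if (fires(mid)) hi_pA <- mid else lo_pA <- mid
  }
  (lo_pA + hi_pA) / 2
}

#' Measure an f-I curve
#'
#' Runs 1 s current steps spanning a multiple range of the rheobase (default
#' 0.9-2.0 in 12 levels, mirroring the granule-cell protocol) and measures
#' the steady-state firing frequency of each.
#'
#' @param model a cell model.
#' @param clamp optional [clamp_config()].
#' @param I_pA explicit current levels (pA); default from `rheobase_pA`.
#' @param rheobase_pA rheobase used to build the default grid; estimated by
#'   [rheobase_from_ramp()] when missing.
#' @param range_rheo relative range of the default grid.
#' @param n_levels number of current levels.
#' @param step_ms step duration (ms).
#' @param sim_dt_ms integration step (ms).
#' @param record_dt_ms recording interval (ms).
#' @return list with `points` (data frame `I_pA`, `f_Hz`), `fit` (a
#'   `cc_fi_fit`) and `rheobase_est_pA`.
#' @export
fi_curve <- function(model, clamp = NULL, I_pA = NULL, rheobase_pA = NULL,
                     range_rheo = c(0.9, 2.0), n_levels = 12,
                     step_ms = 1000, sim_dt_ms = 0.001,
                     record_dt_ms = 0.05) {
  if (is.null(I_pA)) {
    if (is.null(rheobase_pA))
      rheobase_pA <- rheobase_from_ramp(model, clamp)
    I_pA <- seq(range_rheo[1], range_rheo[2], length.out = n_levels) *
      rheobase_pA
  }
  onset <- 100
  f <- vapply(I_pA, function(I) {
    stim <- stim_step(I, onset_ms = onset, offset_ms = onset + step_ms)
    tr <- if (is.null(clamp))
      integrate_model(model, stim, onset + step_ms, sim_dt_ms,
                      record_dt_ms = record_dt_ms)
    else run_clamped(model, clamp, stim, onset + step_ms, sim_dt_ms,
                     record_dt_ms = record_dt_ms)
    firing_frequency(tr, c(onset, onset + step_ms))
  }, numeric(1))
  pts <- data.frame(I_pA = I_pA, f_Hz = f)
  fit <- tryCatch(fit_fi(pts$I_pA, pts$f_Hz), error = function(e) NULL)
  list(points = pts, fit = fit, rheobase_est_pA = rheobase_pA)
}
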