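#' Clamp configuration
#'
#' Settings of the capacitance-clamp controller. Each cycle (every
#' `1/f_dyn_kHz` ms) the controller samples the membrane potential, estimates
#' the membrane current from the voltage derivative and the previously
#' injected clamp current, and injects
#' \deqn{I_{dyn,i} = \frac{C_c - C_t}{C_t}\left(C_c \frac{V_i - V_{i-1}}{\Delta t} - I_{prev}\right)}
#' held constant until the next cycle (zero-order hold). `I_prev` is
#' `I_{dyn,i-1}` in zero-delay mode or `I_{dyn,i-2}` in one-cycle mode (for
#' acquisition systems where the available voltage sample is one cycle old).
#'
#' @param Cc_pF measured capacitance of the electrode compartment (pF).
#' @param Ct_pF target capacitance (pF).
#' @param f_dyn_kHz clamp update frequency (kHz); the sampling interval is
#'   `1/f_dyn_kHz` ms.
#' @param delay_mode `"zero-delay"` (default) or `"one-cycle"`.
#' @param current_limit_pA safety bound on `|I_dyn|`; clipping events are
#'   counted and reported. Default 10 nA.
#' @param noise_sd_mV optional Gaussian noise added to each voltage sample
#'   seen by the controller (emulates recording noise; default 0).
#' @return a `cc_clamp_config`.
#' @export
clamp_config <- function(Cc_pF, Ct_pF, f_dyn_kHz = 20,
                         delay_mode = c("zero-delay", "one-cycle"),
                         current_limit_pA = 10000, noise_sd_mV = 0) {
  if (!(Cc_pF > 0) || !(Ct_pF > 0) || !(f_dyn_kHz > 0))
    stop("Cc, Ct and f_dyn must be positive")
  if (!is.null(current_limit_pA) && current_limit_pA <= 0)
    stop("current limit must be positive when set")
  delay_mode <- match.arg(delay_mode)
  structure(list(Cc_pF = Cc_pF, Ct_pF = Ct_pF, f_dyn_kHz = f_dyn_kHz,
                 dt_ms = 1 / f_dyn_kHz, delay_mode = delay_mode,
                 current_limit_pA = current_limit_pA,
                 noise_sd_mV = noise_sd_mV),
            class = "cc_clamp_config")
}

#' @export
print.cc_clamp_config <- function(x, ...) {
  cat("<clamp config> Cc =", x$Cc_pF, "pF -> Ct =", x$Ct_pF, "pF @",
      x$f_dyn_kHz, "kHz,", x$delay_mode, "\n")
  invisible(x)
}

#' Initial controller state
#'
#' @param V0_mV first voltage sample (mV); the controller starts with
#'   `V_{i-1} = V_0` and `I_dyn = 0`, the unique choice with no startup
#'   transient at rest.
#' @return a `cc_clamp_state`.
#' @export
clamp_state_init <- function(V0_mV) {
  structure(list(V_prev_mV = V0_mV, I_prev1_pA = 0, I_prev2_pA = 0,
                 step = 0L, clip_count = 0L),
            class = "cc_clamp_state")
}

#' One controller update
#'
#' Pure-R reference implementation of a single clamp cycle; the compiled
#' simulation loop in [run_clamped()] performs the identical computation.
#'
#' @param V_mV sampled membrane potential (mV).
#' @param state a `cc_clamp_state`.
#' @param cfg a [clamp_config()].
#' @return list with `I_dyn_pA` and the updated `state`.
#' @export
capclamp_update <- function(V_mV, state, cfg) {
  stopifnot(inherits(state, "cc_clamp_state"), inherits(cfg, "cc_clamp_config"))
  if (!is.finite(V_mV)) stop("non-finite voltage sample")
  I_prev <- if (cfg$delay_mode == "one-cycle") state$I_prev2_pA else state$I_prev1_pA
  I_mem <- estimate_membrane_current(V_mV, state$V_prev_mV, I_prev,
                                     cfg$Cc_pF, cfg$dt_ms)
  I_dyn <- (cfg$Cc_pF - cfg$Ct_pF) / cfg$Ct_pF * I_mem
  if (!is.null(cfg$current_limit_pA) && abs(I_dyn) > cfg$current_limit_pA) {
    I_dyn <- sign(I_dyn) * cfg$current_limit_pA
    state$clip_count <- state$clip_count + 1L
  }
  state$I_prev2_pA <- state$I_prev1_pA
  state$I_prev1_pA <- I_dyn
  state$V_prev_mV <- V_mV
  state$step <- state$step + 1L
  list(I_dyn_pA = I_dyn, state = state)
}

#' Membrane-current estimate from sampled voltage
#'
#' The controller's estimate of the membrane current at the previous sample,
#' `Cc * (V_i - V_{i-1}) / dt - I_dyn,i-1`; exposed separately for
#' diagnostics.
#'
#' @param V_mV,V_prev_mV present and previous voltage samples (mV).
#' @param I_dyn_prev_pA previously injected clamp current (pA).
#' @param Cc_pF cell capacitance used by the controller (pF).
#' @param dt_ms sampling interval (ms).
#' @return estimated membrane current (pA).
#' @export
estimate_membrane_current <- function(V_mV, V_prev_mV, I_dyn_prev_pA,
                                      Cc_pF, dt_ms) {
  stopifnot(dt_ms > 0)
  if (any(!is.finite(c(V_mV, V_prev_mV, I_dyn_prev_pA))))
    stop("non-finite input")
  Cc_pF * (V_mV - V_prev_mV) / dt_ms - I_dyn_prev_pA
}

#' Run a model with the capacitance clamp attached
#'
#' Integrates the model at `sim_dt_ms` while the clamp samples the electrode
#' voltage and refreshes its current every clamp cycle (`1/f_dyn` ms, an
#' integer multiple of `sim_dt_ms`), holding it constant in between.
#'
#' @param model a cell model.
#' @param cfg a [clamp_config()].
#' @param stimulus a `cc_stimulus`.
#' @param duration_ms simulation duration (ms).
#' @param sim_dt_ms integration step (ms); must divide the clamp interval.
#' @param record_dt_ms recording interval (default `sim_dt_ms`).
#' @param initial_state optional starting state.
#' @param record_currents record per-ion currents (Wang-Buzsaki model).
#' @return a [cc_trace()] with channels `V_mV`, `Iext_pA`, `Idyn_pA` (plus
#'   model-specific channels); attributes `clip_count` and
#'   `n_clamp_updates`, and `unstable = TRUE` if more than 1\% of updates hit
#'   the current limit.
#' @export
run_clamped <- function(model, cfg, stimulus, duration_ms, sim_dt_ms,
                        record_dt_ms = sim_dt_ms, initial_state = NULL,
                        record_currents = FALSE) {
  stopifnot(inherits(model, "cc_model"), inherits(cfg, "cc_clamp_config"))
  every <- cfg$dt_ms / sim_dt_ms
  if (abs(every - round(every)) > 1e-6)
    stop("clamp interval (", cfg$dt_ms,
         " ms) must be an integer multiple of sim_dt_ms")
  every <- as.integer(round(every))
  if (every < 1) stop("sim_dt_ms must not exceed the clamp interval")
  if (is.null(initial_state)) initial_state <- steady_state(model, 0)
  method_code <- if (inherits(model, "cc_cable")) 1L else 0L
  record_every <- max(1L, as.integer(round(record_dt_ms / sim_dt_ms)))
  cl <- list(Cc_pF = cfg$Cc_pF, Ct_pF = cfg$Ct_pF, every = every,
             delay_mode = if (cfg$delay_mode == "one-cycle") 1L else 0L,
             limit_pA = cfg$current_limit_pA,
             noise_sd_mV = cfg$noise_sd_mV)
  res <- sim_core(model$type_code, model$pars, unclass(stimulus),
                  duration_ms, sim_dt_ms, method_code, record_every,
                  as.numeric(initial_state), cl,
                  record_currents = record_currents)
  tr <- finish_sim(res, model, sim_dt_ms * record_every, record_currents)
  unstable <- res$n_updates > 0 && res$clip_count / res$n_updates > 0.01
  attr(tr, "unstable") <- unstable
  if (unstable)
    warning("clamp current hit the limit in ",
            round(100 * res$clip_count / res$n_updates, 1),
            "% of updates; run flagged unstable")
  tr
}
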