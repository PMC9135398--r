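#' Cell models
#'
#' Constructors for the cell models the clamp is exercised on. All models
#' share the unit convention (mV, ms, pA, pF, MOhm); conductance-based model
#' parameters are given as specific values (uF/cm2, mS/cm2) together with a
#' membrane area and converted to absolute values internally.
#'
#' @name cellmodels
NULL

#' @rdname cellmodels
#' @param R_MOhm membrane resistance (MOhm).
#' @param C_pF membrane capacitance (pF).
#' @param E_rest_mV resting potential (mV).
#' @return a model object (classed list) accepted by [integrate_model()],
#'   [steady_state()] and [run_clamped()].
#' @export
rc_circuit <- function(R_MOhm, C_pF, E_rest_mV = 0) {
  stopifnot(R_MOhm > 0, C_pF > 0)
  structure(list(R_MOhm = R_MOhm, C_pF = C_pF, E_rest_mV = E_rest_mV,
                 type_code = 0L, n_state = 1L,
                 pars = c(R_MOhm, C_pF, E_rest_mV)),
            class = c("cc_rc", "cc_model"))
}

#' @rdname cellmodels
#' @param Cn_pF,Rn_MOhm near (somatic) compartment capacitance and resistance.
#' @param Ra_MOhm coupling resistance between compartments.
#' @param Cf_pF,Rf_MOhm far (dendritic) compartment capacitance and resistance.
#' @param k clamping factor recorded with the circuit; under the uniformity
#'   assumption the construction satisfies `Rn*Cn = k*Rf*Cf`.
#' @param check_uniform if `TRUE`, verify the `Rn*Cn = k*Rf*Cf` constraint to
#'   relative tolerance 1e-9 (used for circuits built under the uniform
#'   time-constant assumption; arbitrary circuits pass `FALSE`).
#' @export
two_compartment <- function(Cn_pF, Rn_MOhm, Ra_MOhm, Cf_pF, Rf_MOhm,
                            k = 1, E_rest_mV = 0, check_uniform = FALSE) {
  vals <- c(Cn_pF, Rn_MOhm, Ra_MOhm, Cf_pF, Rf_MOhm)
  if (any(vals <= 0) || k <= 0) stop("circuit parameters and k must be positive")
  if (check_uniform) {
    rel <- abs(Rn_MOhm * Cn_pF - k * Rf_MOhm * Cf_pF) / (Rn_MOhm * Cn_pF)
    if (rel > 1e-9)
      stop("uniform time-constant constraint Rn*Cn = k*Rf*Cf violated (rel. ",
           format(rel), ")")
  }
  structure(list(Cn_pF = Cn_pF, Rn_MOhm = Rn_MOhm, Ra_MOhm = Ra_MOhm,
                 Cf_pF = Cf_pF, Rf_MOhm = Rf_MOhm, k = k,
                 E_rest_mV = E_rest_mV,
                 type_code = 1L, n_state = 2L,
                 pars = c(Cn_pF, Rn_MOhm, Ra_MOhm, Cf_pF, Rf_MOhm, E_rest_mV)),
            class = c("cc_two_compartment", "cc_model"))
}

#' @rdname cellmodels
#' @param Cm_uF_cm2 specific membrane capacitance (uF/cm2).
#' @param area_um2 membrane area (um2).
#' @param gNa_mS_cm2,gK_mS_cm2,gL_mS_cm2 peak conductances (mS/cm2).
#' @param ENa_mV,EK_mV,EL_mV reversal potentials (mV).
#' @param phi temperature factor applied to the h and n gating kinetics.
#' @details The Wang-Buzsaki interneuron model uses an instantaneous sodium
#'   activation gate `m = m_inf(V)` and dynamic `h` (sodium inactivation) and
#'   `n` (potassium activation) gates; state vector is `(V, h, n)`. At the
#'   defaults the total capacitance `Cm*A` is 150 pF.
#' @export
wb_neuron <- function(Cm_uF_cm2 = 0.75, area_um2 = 20000,
                      gNa_mS_cm2 = 35, gK_mS_cm2 = 9, gL_mS_cm2 = 0.1,
                      ENa_mV = 55, EK_mV = -90, EL_mV = -65, phi = 5) {
  stopifnot(Cm_uF_cm2 > 0, area_um2 > 0)
  # uF/cm2 * um2 = 1e-6 F/cm2 * 1e-8 cm2 = 1e-14 F = 0.01 pF
  C_pF <- Cm_uF_cm2 * area_um2 * 0.01
  # mS/cm2 * um2 = 1e-3 S/cm2 * 1e-8 cm2 = 1e-11 S = 0.01 nS
  g_nS <- c(gNa_mS_cm2, gK_mS_cm2, gL_mS_cm2) * area_um2 * 0.01
  structure(list(Cm_uF_cm2 = Cm_uF_cm2, area_um2 = area_um2, C_pF = C_pF,
                 gNa_mS_cm2 = gNa_mS_cm2, gK_mS_cm2 = gK_mS_cm2,
                 gL_mS_cm2 = gL_mS_cm2, ENa_mV = ENa_mV, EK_mV = EK_mV,
                 EL_mV = EL_mV, phi = phi,
                 type_code = 2L, n_state = 3L,
                 pars = c(C_pF, g_nS, ENa_mV, EK_mV, EL_mV, phi)),
            class = c("cc_wb", "cc_model"))
}

#' Set the total capacitance of a Wang-Buzsaki neuron
#'
#' Convenience for control simulations with a physically altered capacitance:
#' rescales the specific capacitance at fixed area so that `Cm*A = C_pF`.
#'
#' @param model a [wb_neuron()].
#' @param C_pF desired total capacitance (pF).
#' @export
wb_with_capacitance <- function(model, C_pF) {
  stopifnot(inherits(model, "cc_wb"), C_pF > 0)
  wb_neuron(Cm_uF_cm2 = C_pF / (model$area_um2 * 0.01),
            area_um2 = model$area_um2,
            gNa_mS_cm2 = model$gNa_mS_cm2, gK_mS_cm2 = model$gK_mS_cm2,
            gL_mS_cm2 = model$gL_mS_cm2, ENa_mV = model$ENa_mV,
            EK_mV = model$EK_mV, EL_mV = model$EL_mV, phi = model$phi)
}

#' @rdname cellmodels
#' @param soma_diam_um somatic diameter (um); the soma is a single
#'   iso-potential compartment of area `pi*d^2` (sphere).
#' @param dend_length_um,dend_diam_um dendrite length and diameter (um).
#' @param n_seg number of dendritic segments.
#' @param Rm_Ohm_cm2 specific membrane resistance (Ohm cm2).
#' @param Ra_Ohm_cm axial resistivity (Ohm cm).
#' @details The ball-and-stick cable is discretized into the somatic
#'   compartment (the electrode compartment, index 1) plus `n_seg` equal
#'   cylindrical segments; the default segment length is about a tenth of the
#'   electrotonic length constant, which keeps the per-segment coupling time
#'   constant well above the integration step. Integration requires the
#'   exponential Euler method.
#' @export
ball_and_stick <- function(soma_diam_um = 20, dend_length_um = 600,
                           dend_diam_um = 2, n_seg = 12,
                           Cm_uF_cm2 = 0.9, Rm_Ohm_cm2 = 16800,
                           Ra_Ohm_cm = 300, E_rest_mV = 0) {
  stopifnot(soma_diam_um > 0, dend_length_um > 0, dend_diam_um > 0,
            n_seg >= 1, Cm_uF_cm2 > 0, Rm_Ohm_cm2 > 0, Ra_Ohm_cm > 0)
  um2_to_cm2 <- 1e-8
  soma_area_cm2 <- pi * soma_diam_um^2 * um2_to_cm2
  seg_len_um <- dend_length_um / n_seg
  seg_area_cm2 <- pi * dend_diam_um * seg_len_um * um2_to_cm2
  areas <- c(soma_area_cm2, rep(seg_area_cm2, n_seg))
  C_pF <- Cm_uF_cm2 * areas * 1e6          # uF/cm2 * cm2 = uF = 1e6 pF
  gL_nS <- areas / Rm_Ohm_cm2 * 1e9        # S -> nS
  # axial resistance of one segment (Ohm): Ra * L / (pi r^2); soma-dend link
  # uses half a segment on the dendrite side only.
  seg_len_cm <- seg_len_um * 1e-4
  xarea_cm2 <- pi * (dend_diam_um * 1e-4 / 2)^2
  r_seg_Ohm <- Ra_Ohm_cm * seg_len_cm / xarea_cm2
  r_links <- c(r_seg_Ohm / 2, rep(r_seg_Ohm, n_seg - 1))
  gax_nS <- 1e9 / r_links
  structure(list(soma_diam_um = soma_diam_um, dend_length_um = dend_length_um,
                 dend_diam_um = dend_diam_um, n_seg = as.integer(n_seg),
                 Cm_uF_cm2 = Cm_uF_cm2, Rm_Ohm_cm2 = Rm_Ohm_cm2,
                 Ra_Ohm_cm = Ra_Ohm_cm, E_rest_mV = E_rest_mV,
                 total_area_um2 = sum(areas) / um2_to_cm2,
                 C_seg_pF = C_pF, gL_seg_nS = gL_nS, gax_nS = gax_nS,
                 type_code = 3L, n_state = as.integer(n_seg + 1L),
                 pars = c(n_seg + 1, E_rest_mV, C_pF, gL_nS, gax_nS)),
            class = c("cc_cable", "cc_model"))
}

#' @export
print.cc_model <- function(x, ...) {
  cat("<cell model:", class(x)[1], "> states:", x$n_state, "\n")
  invisible(x)
}

#' Total capacitance of a model (pF)
#' @param model a cell model.
#' @export
total_capacitance <- function(model) {
  switch(class(model)[1],
         cc_rc = model$C_pF,
         cc_two_compartment = model$Cn_pF + model$Cf_pF,
         cc_wb = model$C_pF,
         cc_cable = sum(model$C_seg_pF))
}

#' Electrode-compartment capacitance of a model (pF)
#'
#' The capacitance the clamp controller should use as the cell capacitance
#' `Cc`: the full capacitance for iso-potential models, the near (somatic)
#' capacitance for spatially extended ones.
#' @param model a cell model.
#' @export
electrode_capacitance <- function(model) {
  switch(class(model)[1],
         cc_rc = model$C_pF,
         cc_two_compartment = model$Cn_pF,
         cc_wb = model$C_pF,
         cc_cable = model$C_seg_pF[1])
}

#' Model state derivatives
#'
#' Right-hand side of the model's current-balance equation; for the
#' Wang-Buzsaki model the individual ionic currents are exposed on request.
#'
#' @param model a cell model.
#' @param state state vector (length must match the model: RC 1, two-
#'   compartment 2, Wang-Buzsaki 3 = V, h, n, cable `n_seg + 1`).
#' @param I_inj_pA injected current at the electrode compartment (pA).
#' @param currents if `TRUE`, return a list with the derivatives and the
#'   current-balance-signed ionic currents (`INa_pA`, `IK_pA`, `IL_pA`).
#' @return derivative vector (mV/ms and 1/ms), or a list when
#'   `currents = TRUE`.
#' @export
model_derivatives <- function(model, state, I_inj_pA = 0, currents = FALSE) {
  stopifnot(inherits(model, "cc_model"))
  if (length(state) != model$n_state)
    stop("state vector has length ", length(state), " but model needs ",
         model$n_state)
  bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite state entry at position ", bad[1])
  if (model$type_code == 3L) {
    # cable: leak + axial currents, electrode current at the soma
    V <- state
    E <- model$E_rest_mV
    Il <- model$gL_seg_nS * (E - V)
    N <- model$n_state
    Iax <- c(0, model$gax_nS * (V[-N] - V[-1]))         # into segment i from i-1
    Iax_out <- c(model$gax_nS * (V[-N] - V[-1]), 0)     # out of segment i to i+1
    Iin <- Il + Iax - Iax_out
    Iin[1] <- Iin[1] + I_inj_pA
    dV <- Iin / model$C_seg_pF
    if (currents) return(list(dxdt = dV)) else return(dV)
  }
  out <- deriv_cpp(model$type_code, model$pars, as.numeric(state), I_inj_pA)
  if (currents) out else out$dxdt
}

#' Steady state of a model under a holding current
#'
#' @param model a cell model.
#' @param I_hold_pA holding current at the electrode compartment (pA).
#' @param tol derivative norm tolerance for the returned state.
#' @return state vector with all derivatives below `tol`.
#' @details Passive models are solved linearly; for the Wang-Buzsaki model the
#'   gating variables are set to their voltage steady states and the resting
#'   voltage found by a root solve of the current balance. If no sub-threshold
#'   fixed point exists (holding current at or above rheobase) an error is
#'   raised.
#' @export
steady_state <- function(model, I_hold_pA = 0, tol = 1e-9) {
  stopifnot(inherits(model, "cc_model"))
  st <- switch(class(model)[1],
    cc_rc = model$E_rest_mV + model$R_MOhm * I_hold_pA / 1000,
    cc_two_compartment = {
      E <- model$E_rest_mV
      # DC: far compartment carries no net axial current beyond its leak
      Rdc <- dc_input_resistance(model)
      Vn <- E + Rdc * I_hold_pA / 1000
      # V_f from divider between Ra and Rf
      Vf <- E + (Vn - E) * model$Rf_MOhm / (model$Ra_MOhm + model$Rf_MOhm)
      c(Vn, Vf)
    },
    cc_cable = {
      # solve g V = b
      N <- model$n_state
      g <- diag(model$gL_seg_nS, N)
      for (i in seq_len(N - 1)) {
        ga <- model$gax_nS[i]
        g[i, i] <- g[i, i] + ga; g[i + 1, i + 1] <- g[i + 1, i + 1] + ga
        g[i, i + 1] <- g[i, i + 1] - ga; g[i + 1, i] <- g[i + 1, i] - ga
      }
      b <- model$gL_seg_nS * model$E_rest_mV
      b[1] <- b[1] + I_hold_pA
      as.numeric(solve(g, b))
    },
    cc_wb = {
      dvdt <- function(V) {
        gi <- wb_gating_inf_cpp(V)
        model_derivatives(model, c(V, gi[["h_inf"]], gi[["n_inf"]]),
                          I_hold_pA)[1]
      }
      # scan for a stable sub-threshold fixed point (dV/dt crossing + to -)
      Vs <- seq(-90, -40, by = 0.1)
      d <- vapply(Vs, dvdt, numeric(1))
      idx <- which(d[-length(d)] > 0 & d[-1] <= 0)
      if (!length(idx))
        stop("no sub-threshold fixed point at I_hold = ", I_hold_pA,
             " pA (current at or above rheobase)")
      r <- stats::uniroot(dvdt, c(Vs[idx[1]], Vs[idx[1] + 1]), tol = 1e-12)
      gi <- wb_gating_inf_cpp(r$root)
      c(r$root, gi[["h_inf"]], gi[["n_inf"]])
    })
  d <- model_derivatives(model, st, I_hold_pA)
  if (max(abs(d)) > tol)
    stop("steady-state residual ", format(max(abs(d))), " exceeds tolerance")
  st
}

#' DC input resistance at the electrode compartment (MOhm)
#' @param model a passive cell model.
#' @export
dc_input_resistance <- function(model) {
  switch(class(model)[1],
    cc_rc = model$R_MOhm,
    cc_two_compartment = with(model,
      Rn_MOhm * (Ra_MOhm + Rf_MOhm) / (Rn_MOhm + Ra_MOhm + Rf_MOhm)),
    cc_cable = {
      st0 <- steady_state(model, 0)
      st1 <- steady_state(model, 100)
      (st1[1] - st0[1]) / 100 * 1000
    },
    stop("input resistance undefined for an active model"))
}

#' Integrate a model under a stimulus
#'
#' Fixed-step integration with the second-order Runge-Kutta (midpoint) method
#' or, for the cable model, exponential Euler.
#'
#' @param model a cell model.
#' @param stimulus a `cc_stimulus`.
#' @param duration_ms simulation duration (ms).
#' @param dt_ms integration time step (ms).
#' @param method `"rk2"` or `"exponential-euler"`.
#' @param record_dt_ms recording interval (ms, >= `dt_ms`, default `dt_ms`).
#' @param initial_state starting state; default `steady_state(model, 0)`.
#' @param record_currents record per-ion currents (Wang-Buzsaki model).
#' @param external_current_source optional callback `function(t_ms, V_mV)`
#'   returning a current in pA, evaluated once per simulation step and held
#'   constant until the next call. This is the contract through which the
#'   clamp controller (or any other closed-loop current) attaches; the
#'   built-in clamp of [run_clamped()] uses a compiled equivalent.
#' @return a [cc_trace()].
#' @export
integrate_model <- function(model, stimulus, duration_ms, dt_ms,
                            method = if (inherits(model, "cc_cable"))
                              "exponential-euler" else "rk2",
                            record_dt_ms = dt_ms, initial_state = NULL,
                            record_currents = FALSE,
                            external_current_source = NULL) {
  stopifnot(inherits(model, "cc_model"), inherits(stimulus, "cc_stimulus"),
            dt_ms > 0, duration_ms >= dt_ms)
  method_code <- switch(method, "rk2" = 0L, "exponential-euler" = 1L,
                        stop("unknown integration method: ", method))
  if (inherits(model, "cc_cable") && method_code != 1L)
    stop("cable model requires the exponential Euler method")
  if (is.null(initial_state)) initial_state <- steady_state(model, 0)
  record_every <- max(1L, as.integer(round(record_dt_ms / dt_ms)))
  res <- sim_core(model$type_code, model$pars, unclass(stimulus),
                  duration_ms, dt_ms, method_code, record_every,
                  as.numeric(initial_state), NULL,
                  record_currents = record_currents,
                  ext_src = external_current_source)
  finish_sim(res, model, dt_ms * record_every, record_currents)
}

# shared post-processing of sim_core results
finish_sim <- function(res, model, record_dt, record_currents) {
  if (isTRUE(res$diverged))
    stop("integration diverged (non-finite state) at t = ",
         format(res$t_fail), " ms")
  m <- res$trace
  nms <- c("time_ms", "V_mV", "Iext_pA", "Idyn_pA")
  if (record_currents) nms <- c(nms, "INa_pA", "IK_pA", "IL_pA")
  extra <- switch(class(model)[1],
                  cc_wb = c("h", "n"),
                  cc_two_compartment = "Vf_mV",
                  cc_cable = paste0("Vseg", seq_len(model$n_state - 1), "_mV"),
                  character(0))
  colnames(m) <- c(nms, extra)
  tr <- cc_trace(as.data.frame(m), record_dt)
  attr(tr, "clip_count") <- res$clip_count
  attr(tr, "n_clamp_updates") <- res$n_updates
  tr
}
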