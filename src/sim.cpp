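// Compiled integration core.
//
// Unit system throughout: mV, ms, pA, pF, MOhm, nS.  In these units
// pF * mV/ms = pA and pF/nS = ms; the only conversion factor needed is
// mV/MOhm = nA = 1000 pA, handled where a resistance enters a current.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double MV_PER_MOHM_TO_PA = 1000.0;

// ---------------------------------------------------------------------------
// Stimulus evaluation (zero-order semantics match the R-side constructors)

struct Stim {
  int kind;            // 0 step, 1 pulse_train, 2 ramp, 3 sinusoid, 4 samples
  double onset, offset, amp;
  double width, isi;   // pulse train
  int count;
  double ramp_dur, height;
  double freq_hz, baseline;
  NumericVector samples;
  double sample_dt;

  double eval(double t) const {
    switch (kind) {
    case 0:
      return (t >= onset && t < offset) ? amp : 0.0;
    case 1: {
      if (t < onset) return 0.0;
      double u = t - onset;
      double period = width + isi;
      int k = (int)std::floor(u / period);
      if (k >= count) return 0.0;
      return (u - k * period < width) ? amp : 0.0;
    }
    case 2: {
      if (t < onset || t >= onset + ramp_dur) return 0.0;
      return height * (t - onset) / ramp_dur;
    }
    case 3: {
      if (t < onset || t >= offset) return 0.0;
      return baseline + amp * std::sin(2.0 * M_PI * freq_hz * (t - onset) / 1000.0);
    }
    case 4: {
      double u = t - onset;
      if (u < 0.0) return 0.0;
      int idx = (int)std::floor(u / sample_dt);
      if (idx >= samples.size()) return 0.0;
      return samples[idx];
    }
    }
    return 0.0;
  }
};

static Stim make_stim(const List& s) {
  Stim st;
  st.kind = as<int>(s["kind_code"]);
  st.onset = as<double>(s["onset_ms"]);
  st.offset = s.containsElementNamed("offset_ms") ? as<double>(s["offset_ms"]) : R_PosInf;
  st.amp = s.containsElementNamed("amplitude_pA") ? as<double>(s["amplitude_pA"]) : 0.0;
  st.width = s.containsElementNamed("width_ms") ? as<double>(s["width_ms"]) : 0.0;
  st.isi = s.containsElementNamed("isi_ms") ? as<double>(s["isi_ms"]) : 0.0;
  st.count = s.containsElementNamed("count") ? as<int>(s["count"]) : 0;
  st.ramp_dur = s.containsElementNamed("ramp_duration_ms") ? as<double>(s["ramp_duration_ms"]) : 0.0;
  st.height = s.containsElementNamed("height_pA") ? as<double>(s["height_pA"]) : 0.0;
  st.freq_hz = s.containsElementNamed("freq_Hz") ? as<double>(s["freq_Hz"]) : 0.0;
  st.baseline = s.containsElementNamed("baseline_pA") ? as<double>(s["baseline_pA"]) : 0.0;
  if (s.containsElementNamed("samples_pA")) {
    st.samples = as<NumericVector>(s["samples_pA"]);
    st.sample_dt = as<double>(s["sample_dt_ms"]);
  } else {
    st.sample_dt = 1.0;
  }
  return st;
}

// ---------------------------------------------------------------------------
// Wang-Buzsaki gating rates (1/ms, V in mV); singularities removable.

static inline double wb_am(double V) {
  double x = V + 35.0;
  if (std::fabs(x) < 1e-7) return 1.0;  // limit of 0.1*x/(1-exp(-x/10))
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double wb_bm(double V) { return 4.0 * std::exp(-(V + 60.0) / 18.0); }
static inline double wb_ah(double V) { return 0.07 * std::exp(-(V + 58.0) / 20.0); }
static inline double wb_bh(double V) { return 1.0 / (std::exp(-0.1 * (V + 28.0)) + 1.0); }
static inline double wb_an(double V) {
  double x = V + 34.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double wb_bn(double V) { return 0.125 * std::exp(-(V + 44.0) / 80.0); }

// [[Rcpp::export]]
NumericVector wb_gating_inf_cpp(double V) {
  double am = wb_am(V), bm = wb_bm(V);
  double ah = wb_ah(V), bh = wb_bh(V);
  double an = wb_an(V), bn = wb_bn(V);
  return NumericVector::create(_["m_inf"] = am / (am + bm),
                               _["h_inf"] = ah / (ah + bh),
                               _["n_inf"] = an / (an + bn));
}

// ---------------------------------------------------------------------------
// Model derivative kernels. Parameters are flat numeric vectors built in R.
// model_type: 0 RC (p = R, C, E)
//             1 two-compartment (p = Cn, Rn, Ra, Cf, Rf, E)
//             2 Wang-Buzsaki (p = C_pF, gNa_nS, gK_nS, gL_nS, ENa, EK, EL, phi)
// I is the total injected current (pA) at the electrode compartment.
// cur (optional, length>=3) receives current-balance-signed ionic currents
// (INa, IK, IL in pA) for the WB model.

static inline void deriv_kernel(int model_type, const double* p,
                                const double* x, double I,
                                double* dx, double* cur) {
  switch (model_type) {
  case 0: {
    double IR = (p[2] - x[0]) * MV_PER_MOHM_TO_PA / p[0];
    dx[0] = (IR + I) / p[1];
    if (cur) { cur[0] = 0.0; cur[1] = 0.0; cur[2] = IR; }
    break;
  }
  case 1: {
    double Cn = p[0], Rn = p[1], Ra = p[2], Cf = p[3], Rf = p[4], E = p[5];
    double In = (E - x[0]) * MV_PER_MOHM_TO_PA / Rn;
    double If = (E - x[1]) * MV_PER_MOHM_TO_PA / Rf;
    double Ia = (x[1] - x[0]) * MV_PER_MOHM_TO_PA / Ra;  // far -> near
    dx[0] = (In + Ia + I) / Cn;
    dx[1] = (If - Ia) / Cf;
    if (cur) { cur[0] = 0.0; cur[1] = 0.0; cur[2] = In; }
    break;
  }
  case 2: {
    double C = p[0], gNa = p[1], gK = p[2], gL = p[3];
    double ENa = p[4], EK = p[5], EL = p[6], phi = p[7];
    double V = x[0], h = x[1], n = x[2];
    double am = wb_am(V), bm = wb_bm(V);
    double m = am / (am + bm);
    double INa = -gNa * m * m * m * h * (V - ENa);   // current-balance sign
    double IK = -gK * n * n * n * n * (V - EK);
    double IL = -gL * (V - EL);
    dx[0] = (INa + IK + IL + I) / C;
    dx[1] = phi * (wb_ah(V) * (1.0 - h) - wb_bh(V) * h);
    dx[2] = phi * (wb_an(V) * (1.0 - n) - wb_bn(V) * n);
    if (cur) { cur[0] = INa; cur[1] = IK; cur[2] = IL; }
    break;
  }
  }
}

// [[Rcpp::export]]
List deriv_cpp(int model_type, NumericVector pars, NumericVector state, double I) {
  int n = state.size();
  NumericVector dx(n);
  double cur[3] = {0, 0, 0};
  deriv_kernel(model_type, pars.begin(), state.begin(), I, dx.begin(), cur);
  return List::create(_["dxdt"] = dx,
                      _["INa_pA"] = cur[0], _["IK_pA"] = cur[1], _["IL_pA"] = cur[2]);
}

// ---------------------------------------------------------------------------
// Main fixed-step integrator with optional discrete-time capacitance clamp.
//
// method: 0 = midpoint RK2, 1 = exponential Euler (cable only, model_type 3).
// For model_type 3 (cable) pars layout: [N, EL, C_1..C_N, gL_1..gL_N,
// gax_1..gax_{N-1}] with gax_i coupling segments i and i+1.
//
// Clamp (list or NULL): Cc_pF, Ct_pF, every (sim steps per clamp cycle),
// delay_mode (0 zero-delay, 1 one-cycle), limit_pA, noise_sd_mV.
// Controller: I_i = (Cc-Ct)/Ct * (Cc*(V_i - V_{i-1})/dt_clamp - I_prev)
// with I_prev = I_{i-1} (zero-delay) or I_{i-2} (one-cycle); zero-order hold.

// [[Rcpp::export]]
List sim_core(int model_type, NumericVector pars, List stim,
              double duration, double dt, int method, int record_every,
              NumericVector init, Nullable<List> clamp,
              bool record_currents = false,
              Nullable<Function> ext_src = R_NilValue, int ext_every = 1) {
  Stim st = make_stim(stim);
  int nstate = init.size();
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> xm(nstate), k1(nstate), k2(nstate);

  // cable layout
  int N = 0;
  const double* cab_C = nullptr;
  const double* cab_gL = nullptr;
  const double* cab_gax = nullptr;
  double cab_EL = 0.0;
  if (model_type == 3) {
    N = (int)pars[0];
    cab_EL = pars[1];
    cab_C = pars.begin() + 2;
    cab_gL = pars.begin() + 2 + N;
    cab_gax = pars.begin() + 2 + 2 * N;
    if (nstate != N) stop("cable state dimension mismatch");
    if (method != 1) stop("cable model requires exponential Euler");
  }

  // clamp setup
  bool clamped = clamp.isNotNull();
  double Cc = 0, Ct = 0, beta = 0, dt_clamp = 0, limit = R_PosInf, noise_sd = 0;
  int every = 1, delay_mode = 0;
  double Vprev = x[0], Iprev1 = 0.0, Iprev2 = 0.0, Idyn = 0.0;
  long clip_count = 0, n_updates = 0;
  if (clamped) {
    List cl(clamp);
    Cc = as<double>(cl["Cc_pF"]);
    Ct = as<double>(cl["Ct_pF"]);
    every = as<int>(cl["every"]);
    delay_mode = as<int>(cl["delay_mode"]);
    if (cl.containsElementNamed("limit_pA") && !Rf_isNull(cl["limit_pA"]))
      limit = as<double>(cl["limit_pA"]);
    if (cl.containsElementNamed("noise_sd_mV"))
      noise_sd = as<double>(cl["noise_sd_mV"]);
    beta = (Cc - Ct) / Ct;
    dt_clamp = every * dt;
  }

  bool has_ext = ext_src.isNotNull();
  Function fext = has_ext ? Function(ext_src) : Function(Rf_findFun(Rf_install("identity"), R_GlobalEnv));
  double Iext_cb = 0.0;

  long n_steps = (long)std::llround(duration / dt);
  long n_rec = n_steps / record_every + 1;
  int extra = record_currents ? 3 : 0;
  int ncol = 4 + extra + (nstate - 1);  // t, V, Iext, Idyn, [INa IK IL], other states
  NumericMatrix out(n_rec, ncol);
  long irec = 0;

  bool diverged = false;
  double t_fail = NA_REAL;
  double cur[3] = {0, 0, 0};

  double t = 0.0;
  for (long step = 0; step <= n_steps; ++step) {
    t = step * dt;

    // clamp update at cycle boundaries (including step 0: V_{-1} := V_0)
    if (clamped && step % every == 0) {
      double Vs = x[0];
      if (noise_sd > 0.0) Vs += noise_sd * R::norm_rand();
      double Iprev = (delay_mode == 1) ? Iprev2 : Iprev1;
      double Imem = Cc * (Vs - Vprev) / dt_clamp - Iprev;
      double Inew = beta * Imem;
      if (Inew > limit) { Inew = limit; ++clip_count; }
      else if (Inew < -limit) { Inew = -limit; ++clip_count; }
      if (step == 0) Inew = 0.0;  // V_{-1} = V_0 and I_{-1} = 0 by convention
      Idyn = Inew;
      Iprev2 = Iprev1;
      Iprev1 = Idyn;
      Vprev = Vs;
      ++n_updates;
    }

    if (has_ext && step % ext_every == 0)
      Iext_cb = as<double>(fext(t, x[0]));

    double Iext = st.eval(t) + Iext_cb;
    double Iinj = Iext + Idyn;

    // record
    if (step % record_every == 0 && irec < n_rec) {
      if (record_currents)
        deriv_kernel(model_type, pars.begin(), x.data(), Iinj, k1.data(), cur);
      out(irec, 0) = t;
      out(irec, 1) = x[0];
      out(irec, 2) = Iext;
      out(irec, 3) = Idyn;
      int c = 4;
      if (record_currents) { out(irec, c++) = cur[0]; out(irec, c++) = cur[1]; out(irec, c++) = cur[2]; }
      for (int j = 1; j < nstate; ++j) out(irec, c++) = x[j];
      ++irec;
    }
    if (step == n_steps) break;

    // advance one step
    if (method == 0) {
      deriv_kernel(model_type, pars.begin(), x.data(), Iinj, k1.data(), nullptr);
      double tm = t + 0.5 * dt;
      double Iinj_m = st.eval(tm) + Iext_cb + Idyn;
      for (int j = 0; j < nstate; ++j) xm[j] = x[j] + 0.5 * dt * k1[j];
      deriv_kernel(model_type, pars.begin(), xm.data(), Iinj_m, k2.data(), nullptr);
      for (int j = 0; j < nstate; ++j) x[j] += dt * k2[j];
    } else {
      // exponential Euler, cable
      for (int j = 0; j < N; ++j) xm[j] = x[j];
      for (int j = 0; j < N; ++j) {
        double g = cab_gL[j];
        double b = cab_gL[j] * cab_EL;
        if (j > 0) { g += cab_gax[j - 1]; b += cab_gax[j - 1] * xm[j - 1]; }
        if (j < N - 1) { g += cab_gax[j]; b += cab_gax[j] * xm[j + 1]; }
        if (j == 0) b += Iinj;
        double Vinf = b / g;
        double tau = cab_C[j] / g;  // pF/nS = ms
        x[j] = Vinf + (xm[j] - Vinf) * std::exp(-dt / tau);
      }
    }

    if (!std::isfinite(x[0]) || std::fabs(x[0]) > 1e6) {
      diverged = true;
      t_fail = t + dt;
      break;
    }
  }

  return List::create(_["trace"] = out, _["n_recorded"] = (double)irec,
                      _["clip_count"] = (double)clip_count,
                      _["n_updates"] = (double)n_updates,
                      _["diverged"] = diverged, _["t_fail"] = t_fail);
}
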