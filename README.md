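# capclamp

Membrane capacitance sets how fast a neuron's voltage can change, yet unlike
ionic conductances it has been essentially impossible to manipulate in an
experiment. The **capacitance clamp** closes that gap: a dynamic-clamp
feedback loop samples the membrane potential every cycle, estimates the
momentary membrane current from the voltage derivative and the previously
injected current, and injects a correction current that makes the cell
behave as if its capacitance were a chosen target value

```
I_dyn[i] = (Cc − Ct)/Ct · ( Cc · (V[i] − V[i−1])/Δt − I_dyn[i−1] ),
```

where `Cc` is the measured cell capacitance, `Ct` the target, and
`Δt = 1/f_dyn` the update interval. This package is a simulation toolkit for
that technique and for the measurements around it:

* **Cell models** — RC circuit, two-compartment (near/far) circuit,
  Wang–Buzsáki fast-spiking interneuron, and a ball-and-stick cable, with a
  compiled midpoint-RK2 / exponential-Euler integrator (`integrate_model()`).
* **The clamp** — the discrete-time controller with zero-order hold, zero- or
  one-cycle delay, and a logged safety bound (`clamp_config()`,
  `run_clamped()`, `capclamp_update()`).
* **Capacitance measurement** — the 20-pulse charging protocol,
  multi-exponential Levenberg–Marquardt fits with F-test model selection, and
  the bidirectional mapping between a two-exponential charging curve and the
  two-compartment circuit, including the near capacitance
  `Cn = τ0·τ1/(τ1·R0 + τ0·R1)` (`measure_capacitance()`,
  `fit_exponentials()`, `circuit_from_components()`).
* **Electrophysiology analysis** — spike detection and shape features, f-I
  curves with the square-root fit `f = gain·√(I − Irheo)`, the analytic
  `gain ∝ 1/C` prediction, hypothetical rescaled spikes, charge/energy
  metrics `Q+ = C·ΔV_AP` and `QNa`, temporal-integration ratios, and the
  closed-loop impedance of a clamped RC circuit (`detect_spikes()`,
  `fit_fi()`, `clamped_rc_impedance()`).
* **Experiment protocols and fixtures** — end-to-end runs of the RC
  demonstration, the neuron-model characterization, the clamped-measurement
  verification, the saddle-node-loop capacitance sweep, and seeded synthetic
  fixture generation (`run_rc_demo()`, `run_wb_characterization()`,
  `run_measurement_verification()`, `run_snl_sweep()`,
  `generate_fixtures()`).

A thin command-line wrapper lives at `inst/cli/capclamp.R` (subcommands
`run`, `measure`, `rc-demo`, `wb-table1`, `snl-sweep`, `fixtures`).

## Worked example

Clamp a passive model cell (R = 99.4 MΩ, C = 112.3 pF) at 0.6×, 1× and 3×
its capacitance with a 20 kHz loop, and measure each configuration with a
current step:

```r
library(capclamp)
demo <- run_rc_demo(Ct_factors = c(0.6, 1, 3))
round(demo, 2)
#>    Ct_pF tau_ms deltaV_mV R_meas_MOhm C_meas_pF dQ_apparent_pC dQ_total_pC
#> 1  67.38   6.70     -9.94       99.40     67.38          -0.67       -1.12
#> 2 112.30  11.16     -9.94       99.40    112.30          -1.12       -1.12
#> 3 336.90  33.47     -9.94       99.38    336.77          -3.35       -1.12
```

The measured capacitance tracks each target, the time constant scales as
`R·Ct` while the steady-state deflection (−9.94 mV) and resistance stay
fixed, the *apparent* deposited charge (leak + stimulus) scales with the
target capacitance, and the *total* deposited charge — which includes the
clamp current — stays at `Cc·ΔV = −1.12 pC`, reflecting the physically
unchanged capacitance.

The same controller on the spiking interneuron model:

```r
wb <- wb_neuron()                       # 150 pF total capacitance
stim <- stim_step(60, 100, 1100)        # 1 s, 60 pA
tr <- run_clamped(wb, clamp_config(Cc_pF = 150, Ct_pF = 90, f_dyn_kHz = 20),
                  stim, 1100, sim_dt_ms = 0.001, record_dt_ms = 0.05)
firing_frequency(tr, c(100, 1100))
#> [1] 34.35291
```

against 34.86 Hz for a control neuron whose capacitance is physically set to
90 pF — the clamp reproduces the sped-up firing of a genuinely lighter
membrane.

The methods vignette (`vignettes/capclamp-methods.Rmd`) documents the
feedback law, model kinetics, fitting and mapping procedures, analysis
conventions and known limitations.

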