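# acellsim

Conductance-based simulation of electrical activity in human pancreatic
alpha-cells (A-cells), with an electrogenic SGLT2 Na⁺/glucose co-transporter
as a glucose sensor.

## The problem

Glucagon secretion from pancreatic alpha-cells is driven by action
potentials, and the *height* of those action potentials — via the opening of
high-voltage-activated Ca²⁺ channels — controls how much hormone is
released.  Raising glucose depolarizes the alpha-cell (KATP-channel closure
plus an inward Na⁺/glucose co-transport current), voltage-inactivates the
Na⁺ and Ca²⁺ channels that carry the spike upstroke, and thereby *shrinks*
the action potentials and suppresses secretion.  SGLT2 inhibitors such as
dapagliflozin remove the transporter current, let full-height spikes
recover, and raise glucagon secretion at high glucose — a clinically
observed side effect of this drug class.

`acellsim` is for modellers and electrophysiologists who want to simulate
and dissect this mechanism quantitatively.

## The model

* **Membrane**: Hodgkin–Huxley formalism,
  `C_m dV/dt = −(I_NaV + I_CaT + I_CaL + I_CaPQ + I_KA + I_Kdr + I_KATP +
  I_leak + I_SGLT2)`, with Boltzmann gating
  `x∞(V) = 1/(1 + exp((V½ − V)/s))` and first-order relaxation
  `dx/dt = (x∞ − x)/τ(V)`.  Glucose sets the KATP conductance
  (0.15 nS at 1 mM → 0.115 nS at ≥ 6 mM, saturated) and the glucose
  concentration seen by the transporter.
* **SGLT2**: a six-state alternating-access cycle (Parent-type) with 2:1
  Na⁺:glucose coupling, built on a rate matrix that satisfies microscopic
  reversibility exactly.  It produces a sustained inward (depolarizing)
  current, a transient charge movement (outward on depolarization, an
  inward "brake" on repolarization), a glucose influx, and a
  glucose-dependent component of the resting conductance.  Dapagliflozin is
  modelled as complete transporter block (n = 0).
* **Analysis**: action-potential detection (threshold + prominence),
  per-segment amplitude/frequency statistics, background (slope)
  conductance from small clamped voltage steps, voltage-clamp decomposition
  of the transporter current, steady-state glucose flux balance
  (`J_in = (k_out + k_consumption) · G_i`), and plasma-protein-binding dose
  arithmetic.

The compiled (C) right-hand side is integrated with `deSolve`'s stiff
solver; everything is deterministic.  See the methods vignette
(`vignettes/alpha-cell-model.Rmd`) for the science, the calibration story
and known limitations.

## Worked example

```r
library(acellsim)

params <- acell_default_params()
trace  <- simulate_protocol(params, figure2_protocol(segment_s = 10),
                            burn_in_s = 5)
segment_features(trace)[, c("segment", "ap_count", "frequency_hz",
                            "mean_amplitude_mv")]
```

```
    segment ap_count frequency_hz mean_amplitude_mv
1       1mM       18     2.250000          85.92096
2       6mM       82    10.250641          31.68244
3      11mM       89    11.125695          29.01340
4 11mM+dapa       40     5.000313          85.56059
```

Reading this: at 1 mM glucose the cell fires slow, tall action potentials.
Raising glucose to 6 and 11 mM (which lowers g_KATP to 0.115 nS and feeds
more glucose to SGLT2) suppresses spike height; the extra ~3 mV loss from
6 → 11 mM is carried *entirely* by the transporter, since g_KATP is
identical in those segments.  Blocking SGLT2 at 11 mM (`11mM+dapa`)
restores the amplitude to within ~2% of the 1 mM value even though KATP
stays low — the electrogenic, not the metabolic, pathway is what matters.

```r
background_conductance(params, 11, component = "sglt2") -
  background_conductance(params, 1, component = "sglt2")
#> [1] 6.973877  # pS: the SGLT2 share of the resting conductance grows with glucose

flux_balance_analysis(j_in = 50, j_consumption = 5, j_sglt2 = 1.7)$sglt2_share_pct
#> [1] 3.288201 # SGLT2 carries only ~3% of glucose uptake: blocking it cannot
#>            # meaningfully change metabolism or KATP activity
```

A thin command-line front end ships in `inst/cli/acellsim`
(subcommands `simulate`, `figure2`, `figure3`, `clamp-sglt2`,
`analyze-trace`, `conductance`, `flux-balance`, `free-drug`).

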