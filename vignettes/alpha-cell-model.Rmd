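---
title: "Modelling glucose sensing by SGLT2 in human pancreatic alpha-cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucose sensing by SGLT2 in human pancreatic alpha-cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acellsim)
```

## The scientific question

Glucagon-secreting pancreatic alpha-cells (A-cells) are electrically
excitable: glucagon release is driven by action potentials (APs), and the
*height* of those APs — not merely their presence — controls secretion,
because the high-voltage-activated Ca²⁺ channels that trigger exocytosis
only open during large spikes.  Raising extracellular glucose paradoxically
*suppresses* glucagon release even though it depolarizes the cell: the
depolarization inactivates the voltage-gated Na⁺ and Ca²⁺ channels that
carry the AP upstroke, so the spikes become smaller.

Two glucose-sensing pathways act on the membrane in this package's model:

1. **Metabolic**: glucose metabolism raises ATP/ADP and closes ATP-sensitive
   K⁺ (KATP) channels.  This pathway saturates by 6 mM glucose.
2. **Electrogenic transport**: the Na⁺/glucose co-transporter SGLT2 carries
   a net inward (depolarizing) current whose magnitude keeps growing above
   6 mM.  Blocking SGLT2 (pharmacologically, with dapagliflozin) removes
   this current and lets full-height APs recover — the proposed mechanism
   by which SGLT2 inhibitors raise glucagon secretion at high glucose.

`acellsim` implements a Hodgkin–Huxley (HH) conductance-based model of the
human alpha-cell membrane coupled to a six-state kinetic model of
electrogenic SGLT2 transport, plus the analysis layer needed to reproduce
the in-silico observables: glucose-dependent AP-height suppression and its
reversal by SGLT2 block, the transient/sustained decomposition of the
transporter current under voltage clamp, the SGLT2 component of the resting
(background) conductance, and the steady-state glucose flux balance.

## The membrane model

The membrane potential obeys

$$C_m \frac{dV}{dt} = -\left(I_{NaV} + I_{CaT} + I_{CaL} + I_{CaPQ}
  + I_{KA} + I_{Kdr} + I_{KATP} + I_{leak} + I_{SGLT2}\right),$$

with all currents in pA (outward positive), $V$ in mV and $C_m = 5$ pF (a
typical human islet-cell capacitance).  Each voltage-gated current has the
HH form $I_X = g_X\, m_X^{p}\, h_X\, (V - V_X)$; gates relax as
$dx/dt = (x_\infty(V) - x)/\tau_x(V)$ with Boltzmann steady states

$$x_\infty(V) = \frac{1}{1 + \exp\!\big((V_{1/2} - V)/s\big)},$$

where $s > 0$ denotes activation and $s < 0$ inactivation.  Time constants
are either constant or bell-shaped in voltage
($\tau(V) = \tau_{floor} + \tau_{peak}\, e^{-((V - V_c)/w)^2}$).  The
activation exponent is 1 for all channels except the delayed rectifier
($p = 4$).  KATP and leak are purely ohmic.  Reversal potentials are fixed
constants (no Nernst recomputation): intracellular ion pools are not
modelled.

Glucose acts on the membrane twice, via [`glucose_map()`]:

* $g_{KATP}$: 0.15 nS at ≤ 1 mM, 0.115 nS at ≥ 6 mM (closure saturated),
  linearly interpolated between the break points for non-protocol levels;
* $G_{SGLT2}$: the glucose concentration seen by the transporter equals the
  extracellular concentration (identity map).

### Functional roles of the conductances

The packaged channel set was designed around a two-layer architecture:

* a **robust spike engine** — L- and P/Q-type Ca²⁺ currents against the
  delayed rectifier — that keeps oscillating over a wide range of baseline
  potentials, so that AP amplitude *degrades gracefully* rather than
  collapsing when the inter-spike potential is depolarized;
* **amplitude boosters** — the NaV and T-type Ca²⁺ currents — whose steep,
  hyperpolarization-requiring inactivation ($V_{1/2} \approx -47$ mV for
  NaV) converts small changes of the inter-spike trough into large changes
  of spike height.  Their slow recovery from inactivation also makes the
  amplitude sensitive to firing frequency: conditions that fire faster
  recover less NaV between spikes and fire smaller APs.

This architecture is what gives the model its characteristic phenotype: at
1 mM glucose the trough is deep, NaV recovers, and spikes are tall; KATP
closure plus the SGLT2 inward current depolarize the trough at 6/11 mM and
the spikes shrink; removing SGLT2 (dapagliflozin, $n = 0$) restores them
almost fully even though $g_{KATP}$ stays low.

## The SGLT2 six-state model

The transporter follows a Parent-type alternating-access cycle over six
states (outward empty → outward Na-bound → outward Na·glucose-bound →
the same three inward-facing, and back), with 2:1 Na⁺:glucose coupling.
Na⁺ binding/release is treated as concerted, so the Na-binding rates scale
with $[\mathrm{Na}]^2$.  Each forward transition $t$ carries an apparent
valence $z_t$ (inward-positive; $\sum_t z_t = 2$, the charge per cycle).
Charged transitions are scaled by
$\exp(-z_t\,\theta\,FV/RT)$ (forward) and $\exp(+z_t(1-\theta)\,FV/RT)$
(backward).

**Microscopic reversibility** is enforced by construction: the intrinsic
clockwise/counter-clockwise rate products are balanced (the constructor
derives $k_{16}$ from the other eleven rates), so the full cycle-product
ratio equals the thermodynamic factor
$([\mathrm{Na}]_o/[\mathrm{Na}]_i)^2\,(G_o/G_i)\,e^{-2FV/RT}$ and every
current and flux vanishes identically at equilibrium composition.  This is
tested directly.

### Design choices worth knowing about

* **Asymmetric voltage split ($\theta = 1$).**  The classic symmetric
  $FV/2RT$ split caps the steady current's voltage steepness at e-fold per
  ~53 mV for the charge budget available here.  That steepness cannot
  simultaneously reproduce a cycle-averaged glucose influx of ~0.8/1.7
  µM/s *during firing* (membrane mostly near −40 mV) and a ~7 pS increase
  in slope conductance measured at −70 mV: the conductance measurement
  lives two e-folds away from the flux measurement.  Placing the voltage
  dependence on the inward-directed rates ($\theta = 1$, configurable)
  steepens the current–voltage relation enough to reconcile the two.  The
  forward/backward rate *ratio* — and hence all thermodynamics — is
  independent of $\theta$.
* **2:1 stoichiometry.**  With 1:1 coupling the charge moved per
  transported glucose is a single elementary charge, which makes the
  sustained current, the conductance increase and the pre-steady-state
  charge movement mutually starved; the Parent SGLT1 scheme's 2:1 coupling
  is retained.  The coupling ratio is a parameter.
* **A slow translocation bottleneck and a fast, charged binding layer.**
  The sugar-loaded translocation step (3↔4) is orders of magnitude slower
  than every other step and rate-limits the cycle; all other transitions
  equilibrate within ~1 ms.  Consequences: (i) the glucose flux and
  sustained current are set by the bottleneck and calibrate cleanly;
  (ii) the charged, glucose-gated binding layer redistributes
  *quasi-statically* during an AP, so the transporter behaves like a
  glucose-dependent charge reservoir — an outward displacement current
  during the upstroke that clips spike height, and an inward displacement
  current during the downstroke that brakes repolarization.  This is the
  model's mechanistic reading of the transient/sustained decomposition
  seen under voltage clamp, and it is the dominant route by which the
  6 → 11 mM glucose step (identical $g_{KATP}$) lowers AP amplitude.
* **Trans-inhibition decouples the flux- and charge-glucose responses.**
  Intracellular glucose is tied to the extracellular level (GLUT1
  equilibrates it), so raising glucose also loads the inward-facing bound
  state and partially backs up the cycle.  The net flux therefore
  saturates at a lower glucose level than the outward-facing bound pool
  does — the flux pair (0.8/1.7 µM/s at 1/11 mM) and the growing
  charge-movement pool between 6 and 11 mM can both hold.
* **Effective, not single-molecule, parameters.**  Only products such as
  (transporter count × unitary turnover) and (count × valence ×
  occupancy sensitivity) are constrained by the calibration targets; the
  count and per-molecule rates are not separately identifiable.  The
  packaged `n_transporters` and rate constants should be read as effective
  values for the whole-cell charge-movement and flux densities, not as
  molecular measurements.

## Protocols

* [`figure2_protocol()`]: 1 mM → 6 mM → 11 mM glucose → 11 mM +
  dapagliflozin (all transporters blocked, $n = 0$), default 10 s per
  segment, deterministic initial condition (all gates and occupancies at
  their steady state for −70 mV) followed by a discarded 5 s burn-in.
  Parameter changes at segment boundaries are instantaneous.
* [`sglt2_voltage_clamp()`]: piecewise-constant voltage protocols on the
  occupancy master equation; each post-step segment is decomposed into a
  sustained plateau (detected where $|dI/dt| < 10^{-4}$ pA/ms for 5 ms,
  both configurable) and the transient charge $\int (I - I_{sus})\,dt$.
* [`background_conductance()`]: $\Delta I_{steady}/\Delta V$ between
  clamped steady states at −70 and −60 mV, for the whole membrane or the
  SGLT2 component alone.
* [`overexpression_check()`]: the 1 mM protocol with the transporter count
  scaled 5–10×; the output is classified AP-like only if at least 3 spikes
  of ≥ 15 mV mean amplitude are detected.  With the packaged set a 10×
  pool abolishes AP-like activity (depolarization block).

## Analysis layer

AP detection ([`detect_aps()`]) is threshold-plus-prominence: upward
crossings of (trace median + 10 mV) whose peak-minus-preceding-trough
excursion reaches 5 mV.  Median-relative thresholding makes detection
invariant to constant offsets.  Amplitude is defined as peak minus
preceding trough; peak and trough values are also reported separately so
either reading of "AP height" is available.

The flux-balance helper ([`flux_balance_analysis()`]) implements the
steady-state relation $J_{in} + J_{SGLT2} = (k_{out} + k_{consumption})
G_i$: with the literature GLUT1 influx of ~50 µM/s and consumption of
~5 µM/s, GLUT1 must export ~45 µM/s, and the model's SGLT2 influx at
11 mM glucose is only ~3% of total uptake — so blocking SGLT2 lowers
intracellular glucose and consumption by only ~3% (linear-consumption
assumption), far too little to reopen KATP channels.  This motivates the
electrogenic (rather than metabolic) interpretation of dapagliflozin's
effect.  [`free_drug_concentration()`] does the protein-binding
arithmetic: 24–240 nM total dapagliflozin at 93% binding leaves
1.7–17 nM free, spanning the transporter's IC₅₀ — which justifies
modelling therapeutic dapagliflozin as a complete block ($n = 0$) rather
than a partial-occupancy model.

## Numerical choices

* Stiff integration with `deSolve`'s `lsoda` (an `ode15s` analogue),
  `rtol = 1e-8`, `atol = 1e-10`, maximum step 1 ms; dense output at 2 kHz.
  The production right-hand side is compiled C; a plain-R reference
  implementation ([`acell_rhs()`]) is tested against it.
* The SGLT2 steady state is the normalized null-space vector of the rate
  matrix (direct linear solve); it is verified against long-time ODE
  integration on random parameter draws.
* Deterministic throughout: no random numbers are used by the core model,
  so repeated runs are byte-identical.
* Because the translocation bottleneck is slow, the transporter
  distribution re-settles over seconds after each glucose step; the
  protocol analysis therefore discards the first 20% of each segment
  (and the default segments are 10 s long).  Test and example runs use
  shorter segments (2–6 s) where only qualitative behaviour is asserted.

## Calibration status and limitations

The numeric gating parameters, conductances and transporter rate constants
of the original study are not printed in the available text; the packaged
`default` set is a reconstruction, calibrated so that the model's printed
in-silico outputs hold simultaneously: AP amplitude ordering across the
glucose-step protocol with near-complete restoration by dapagliflozin,
an amplitude ~3 mV higher at 6 than at 11 mM glucose, cycle-averaged
SGLT2 glucose fluxes of ~0.8 and ~1.7 µM/s at 1 and 11 mM (0.8 pL cell
volume), a ~7 pS increase of the SGLT2 background-conductance component
from 1 to 11 mM, and loss of AP-like activity at a 5–10× transporter
count.  A second packaged set, `subset-acell`, is a variant with a larger
transporter pool in which APs survive 6 mM but fail at 11 mM glucose —
the behaviour described for a subset of A-cells.

Known limitations:

* **Inter-AP current sign at low glucose.**  Between action potentials the
  packaged model's SGLT2 current is inward at every glucose level (more
  inward at high glucose).  A slightly *outward* between-spike current at
  low glucose, as has been described, is not reproducible here — and, we
  argue, cannot be: over a periodic firing orbit the displacement
  (pre-steady-state) charge integrates to zero, so the between-spike
  transporter current must average approximately
  $-\,\mathrm{stoich}\cdot e \cdot J_{glc}$; a 1 mM glucose influx of
  0.8 µM/s then forces a net inward inter-spike current of roughly
  −0.1 pA in any thermodynamically consistent six-state model.  The
  glucose *gradient* of the inter-spike current (strongly more inward at
  11 than at 1 mM) is reproduced and is what carries the mechanism.
* **Inter-spike minimum at low glucose.**  The calibrated set rests near
  −53 mV between spikes at 1 mM glucose (−35 mV at 6–11 mM); a shallower
  low-glucose minimum cannot be reconciled with the 1 mM flux anchor given
  the voltage steepness the conductance anchor requires.
* **Frequency ordering.**  In the packaged set the firing *rate* increases
  with glucose (the sustained inward current speeds the pacemaker), while
  the amplitude ordering and its pharmacological reversal are reproduced.
  Reports of glucose lowering both amplitude and frequency are not matched
  on the frequency axis; amplitude, which carries the secretion-coupling
  argument, is the calibrated observable.
* No intracellular Ca²⁺ dynamics, stochastic gating, or temperature
  corrections; reversal potentials fixed; no islet-level coupling.
* The transporter parameters are effective whole-cell values (see above);
  per-molecule turnover in the packaged set is far below biochemical
  estimates because the calibration targets only constrain products of
  pool size and rates.
* Secretion itself is not modelled: AP height is the model's terminal
  observable, interpreted through the known steep dependence of glucagon
  exocytosis on spike amplitude.

## Reproducing the headline numbers

`scripts/acceptance.R` re-runs the two protocol-level calculations from
scratch against the installed package — the 6-vs-11 mM amplitude
difference from the glucose-step protocol and the SGLT2
background-conductance increase from clamped 10 mV steps — and writes them
as JSON.  The test suite (`tests/testthat`) asserts the remaining
phenotype (flux pair, orderings, overexpression, clamp decomposition) plus
the thermodynamic, conservation and oracle-equivalence properties.
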