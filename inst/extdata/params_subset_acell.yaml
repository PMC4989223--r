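# Variant parameter set representing a subset of A-cells: a larger SGLT2 pool
# with weaker glucose binding makes action potentials survive 6 mM but fail
# at 11 mM glucose, entirely through SGLT2 glucose sensing.
# All numeric gating parameters, conductances and transporter kinetics are a
# calibration-derived reconstruction (see the provenance block and the
# methods vignette).  Units are fixed package-wide: mV, ms, nS, pA, pF, mM.
units:
  voltage: mV
  time: ms
  conductance: nS
  current: pA
  capacitance: pF
  concentration: mM

cell:
  c_m: 5.0
  v_k: -75.0
  leak: {g_max: 0.0363, v_rev: 0.0}   # non-selective background conductance

glucose_map:
  g_katp_low: 0.15    # nS at <= 1 mM glucose
  g_katp_high: 0.115  # nS at >= 6 mM glucose (KATP closure saturated)
  glucose_low: 1.0
  glucose_high: 6.0

channels:
  NaV:
    g_max: 12.0
    v_rev: 70.0
    activation: {v_half: -15.0, slope: 5.0, tau: 0.1}
    inactivation:
      v_half: -47.0
      slope: -6.26
      tau: {floor: 1.5, peak: 182.0, v_mid: -58.8, width: 21.0}
  CaT:
    g_max: 0.107
    v_rev: 65.0
    activation: {v_half: -50.0, slope: 6.0, tau: 1.0}
    inactivation: {v_half: -55.0, slope: -6.0, tau: 60.0}
  CaL:
    g_max: 0.55
    v_rev: 65.0
    activation: {v_half: -20.0, slope: 5.0, tau: 0.5}
    inactivation: {v_half: -20.0, slope: -7.0, tau: 60.0}
  CaPQ:
    g_max: 0.6
    v_rev: 65.0
    activation: {v_half: -5.0, slope: 6.0, tau: 1.0}
    inactivation: {v_half: -25.0, slope: -12.0, tau: 150.0}
  KA:
    g_max: 1.0
    v_rev: -75.0
    activation: {v_half: -30.0, slope: 10.0, tau: 0.3}
    inactivation: {v_half: -55.0, slope: -5.0, tau: 15.0}
  Kdr:
    g_max: 3.0
    v_rev: -75.0
    activation_exponent: 4
    activation:
      v_half: -25.0
      slope: 7.0
      tau: {floor: 2.5, peak: 12.0, v_mid: -5.0, width: 30.0}

sglt2:
  n_transporters: 14260920
  theta: 1.0          # all voltage dependence on the inward-directed rates
  na_out: 140.0
  na_in: 10.0
  glucose_in: tied    # intracellular glucose tracks extracellular (GLUT1)
  na_stoichiometry: 2
  temperature_c: 37.0
  valences: {z12: 0.266, z23: 0.576, z34: 0.39, z45: 0.311, z56: 0.0, z61: 0.457}
  # per ms; binding rates (k12, k65 for Na+; k23, k54 for glucose) are second
  # order.  k16 is derived from microscopic reversibility and hence omitted.
  rates:
    k12: 1.5e-05
    k21: 0.3
    k23: 2.3
    k32: 30.0
    k34: 7.916740e-05
    k43: 7.916740e-05
    k45: 0.057
    k54: 0.405
    k56: 0.5
    k65: 0.001
    k61: 0.05

provenance:
  channels: >-
    Gating midpoints, slopes and time constants follow the qualitative shapes
    of human and rodent alpha-cell voltage-clamp recordings (steeply
    hyperpolarization-dependent NaV/CaT inactivation, high-voltage-activated
    L- and P/Q-type currents, a raised-exponent delayed rectifier);
    conductances were calibrated so the whole-cell model fires stable action
    potentials whose height is suppressed by glucose and restored by SGLT2
    block.
  glucose_map: >-
    KATP conductances 0.15 nS (1 mM) and 0.115 nS (>= 6 mM) are the
    glucose-step protocol values; linear interpolation between the break
    points is a package choice for non-protocol glucose levels.
  sglt2: >-
    Parent-type alternating-access cycle with 2:1 Na:glucose coupling; the
    zero-voltage rates, apparent valences and transporter count are effective
    whole-cell values calibrated jointly against the model's glucose-flux,
    background-conductance and action-potential-height outputs, and are not
    single-molecule measurements.
  cell: >-
    Membrane capacitance 5 pF is a typical human islet-cell value; the
    non-selective background (leak) conductance and its 0 mV reversal were
    calibrated alongside the channel set.
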