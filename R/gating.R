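#' Boltzmann description of one gating variable
#'
#' A `gating_spec` describes the voltage dependence of one Hodgkin-Huxley
#' activation or inactivation variable: a Boltzmann steady-state curve
#' \eqn{x_\infty(V) = 1/(1 + \exp((V_{1/2} - V)/s))} and a relaxation time
#' constant, either constant or bell-shaped in voltage.
#'
#' Sign convention: `slope > 0` gives a curve increasing with depolarization
#' (activation); `slope < 0` a decreasing curve (inactivation).
#'
#' @param v_half Boltzmann midpoint (mV).
#' @param slope Boltzmann slope factor (mV), non-zero; sign as above.
#' @param tau Relaxation time constant. Either a single positive number (ms)
#'   or a list with fields `floor` (ms), `peak` (ms), `v_mid` (mV), `width`
#'   (mV) describing \eqn{\tau(V) = floor + peak\,e^{-((V - v_{mid})/width)^2}}.
#' @return An object of class `gating_spec`.
#' @examples
#' act <- gating_spec(v_half = -30, slope = 5, tau = 1)
#' boltzmann(-30, act) # 0.5 at the midpoint
#' @export
gating_spec <- function(v_half, slope, tau = 1) {
  stopifnot(is.numeric(v_half), length(v_half) == 1L, is.finite(v_half),
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope == 0) stop("Boltzmann slope factor must be non-zero")
  if (is.numeric(tau)) {
    stopifnot(length(tau) == 1L, is.finite(tau))
    if (tau <= 0) stop("time constant must be positive")
    tau <- list(floor = tau, peak = 0, v_mid = 0, width = 1)
  } else if (is.list(tau)) {
    tau <- tau[c("floor", "peak", "v_mid", "width")]
    if (anyNA(names(tau)) || !all(vapply(tau, is.numeric, logical(1L))))
      stop("voltage-dependent tau needs numeric fields floor, peak, v_mid, width")
    if (tau$floor <= 0 || tau$peak < 0 || tau$width <= 0)
      stop("tau(V) must be positive for all V: need floor > 0, peak >= 0, width > 0")
  } else {
    stop("tau must be a number (ms) or a list(floor, peak, v_mid, width)")
  }
  structure(list(v_half = v_half, slope = slope, tau = tau),
            class = "gating_spec")
}

#' Boltzmann steady-state open fraction
#'
#' @param v Membrane potential (mV); may be a vector.
#' @param spec A [gating_spec()].
#' @return Steady-state open fraction in (0, 1), same length as `v`.
#' @export
boltzmann <- function(v, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    stop("invalid voltage: v must be finite")
  1 / (1 + exp((spec$v_half - v) / spec$slope))
}

#' Gating time constant at a voltage
#'
#' @inheritParams boltzmann
#' @return tau(v) in ms, same length as `v`.
#' @export
gating_tau <- function(v, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  tp <- spec$tau
  tp$floor + tp$peak * exp(-((v - tp$v_mid) / tp$width)^2)
}

#' Relaxation rate of a gating variable
#'
#' Returns \eqn{(x_\infty(V) - x)/\tau(V)}, the time derivative of the gate.
#'
#' @param x Current gate value in \[0, 1\].
#' @param v Membrane potential (mV).
#' @param spec A [gating_spec()].
#' @return dx/dt in 1/ms.
#' @export
gating_rhs <- function(x, v, spec) {
  stopifnot(all(x >= 0), all(x <= 1))
  tau <- gating_tau(v, spec)
  if (any(tau <= 0)) stop("tau(v) <= 0: invalid gating parameters")
  (boltzmann(v, spec) - x) / tau
}

#' Parameters of one Hodgkin-Huxley membrane current
#'
#' @param name Channel identifier (e.g. "NaV", "CaT", "CaL", "CaPQ", "KA",
#'   "Kdr"). Purely ohmic conductances (KATP, leak) are not represented here;
#'   see [katp_leak_current()].
#' @param g_max Maximal whole-cell conductance (nS), non-negative.
#' @param v_rev Reversal potential (mV).
#' @param activation,inactivation [gating_spec()] objects, or `NULL` when the
#'   channel lacks that gate.
#' @param activation_exponent Small positive integer p in \eqn{g\,m^p h (V - V_{rev})}.
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(name, g_max, v_rev, activation = NULL,
                           inactivation = NULL, activation_exponent = 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(g_max), length(g_max) == 1L, is.finite(g_max),
            is.numeric(v_rev), length(v_rev) == 1L, is.finite(v_rev))
  if (g_max < 0) stop("g_max must be >= 0 for channel ", name)
  p <- as.integer(activation_exponent)
  if (is.na(p) || p < 1L) stop("activation_exponent must be a positive integer")
  for (g in list(activation, inactivation))
    if (!is.null(g) && !inherits(g, "gating_spec"))
      stop("activation/inactivation must be gating_spec objects or NULL")
  structure(list(name = name, g_max = g_max, v_rev = v_rev,
                 activation = activation, inactivation = inactivation,
                 activation_exponent = p),
            class = "channel_params")
}

#' Instantaneous Hodgkin-Huxley current
#'
#' \eqn{I = g_{max} m^p h (V - V_{rev})}, outward positive; `m^p` is taken as
#' 1 when the channel has no activation gate and `h` as 1 when it has no
#' inactivation gate. nS times mV gives pA.
#'
#' @param v Membrane potential (mV).
#' @param params A [channel_params()] object.
#' @param m,h Gate values in \[0, 1\]; ignored for absent gates.
#' @return Current in pA (outward positive).
#' @export
channel_current <- function(v, params, m = 1, h = 1) {
  stopifnot(inherits(params, "channel_params"),
            all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  mp <- if (is.null(params$activation)) 1 else m^params$activation_exponent
  he <- if (is.null(params$inactivation)) 1 else h
  params$g_max * mp * he * (v - params$v_rev)
}

#' Steady-state current-voltage relation of one channel
#'
#' Evaluates the current with every gate at its Boltzmann steady state. For
#' channels with both activation and inactivation this produces the classic
#' non-monotone "window current" shape.
#'
#' @inheritParams channel_current
#' @return Steady-state current (pA) at each `v`.
#' @export
channel_current_ss <- function(v, params) {
  m <- if (is.null(params$activation)) 1 else boltzmann(v, params$activation)
  h <- if (is.null(params$inactivation)) 1 else boltzmann(v, params$inactivation)
  channel_current(v, params, m = m, h = h)
}

#' KATP and passive leak currents
#'
#' Both are purely ohmic: \eqn{g_{KATP}(V - V_K) + g_{leak}(V - V_{leak})}.
#'
#' @param v Membrane potential (mV).
#' @param g_katp,g_leak Conductances (nS), non-negative.
#' @param v_k,v_leak Reversal potentials (mV).
#' @return Current in pA (outward positive).
#' @examples
#' katp_leak_current(-70, g_katp = 0.15, g_leak = 0, v_k = -75, v_leak = -20)
#' @export
katp_leak_current <- function(v, g_katp, g_leak, v_k, v_leak) {
  if (g_katp < 0 || g_leak < 0) stop("conductances must be >= 0")
  g_katp * (v - v_k) + g_leak * (v - v_leak)
}
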