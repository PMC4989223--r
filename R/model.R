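## Whole-cell membrane model: V plus twelve gating slots plus six SGLT2
## occupancies.  The production right-hand side lives in src/acell_derivs.c
## (deSolve compiled-model interface); acell_rhs() below is the plain-R
## reference used for cross-checks and for steady-state root finding.

.acell_channel_order <- c("NaV", "CaT", "CaL", "CaPQ", "KA", "Kdr")
.acell_current_names <- c("i_nav", "i_cat", "i_cal", "i_capq", "i_ka",
                          "i_kdr", "i_katp", "i_leak", "i_sglt2")
.acell_gate_names <- as.vector(vapply(
  tolower(.acell_channel_order),
  function(ch) paste(ch, c("m", "h"), sep = "_"), character(2)))

#' Full parameter set of the alpha-cell model
#'
#' @param channels Named list of [channel_params()] objects; must contain
#'   NaV, CaT, CaL, CaPQ, KA and Kdr.
#' @param sglt2 An [sglt2_params()] object.
#' @param c_m Membrane capacitance (pF), positive.
#' @param v_k K+ reversal potential for the KATP current (mV).
#' @param g_leak,v_leak Passive leak conductance (nS) and reversal (mV).
#' @param g_katp_low KATP conductance at and below `glucose_low` (nS).
#' @param g_katp_high KATP conductance at and above `glucose_high` (nS);
#'   KATP closure by glucose is saturated there.
#' @param glucose_low,glucose_high Glucose break points (mM) of the KATP
#'   map; conductance is interpolated linearly in between.
#' @return An object of class `acell_params`.
#' @export
cell_params <- function(channels, sglt2, c_m = 5, v_k = -75,
                        g_leak = 0.02, v_leak = -20,
                        g_katp_low = 0.15, g_katp_high = 0.115,
                        glucose_low = 1, glucose_high = 6) {
  if (c_m <= 0) stop("c_m must be > 0")
  if (g_leak < 0 || g_katp_low < 0 || g_katp_high < 0)
    stop("conductances must be >= 0")
  missing <- setdiff(.acell_channel_order, names(channels))
  if (length(missing))
    stop("missing channels: ", paste(missing, collapse = ", "))
  for (nm in .acell_channel_order)
    if (!inherits(channels[[nm]], "channel_params"))
      stop("channel ", nm, " is not a channel_params object")
  stopifnot(inherits(sglt2, "sglt2_params"), glucose_low < glucose_high)
  structure(list(c_m = c_m, channels = channels[.acell_channel_order],
                 sglt2 = sglt2, v_k = v_k, g_leak = g_leak, v_leak = v_leak,
                 g_katp_low = g_katp_low, g_katp_high = g_katp_high,
                 glucose_low = glucose_low, glucose_high = glucose_high),
            class = "acell_params")
}

#' @export
print.acell_params <- function(x, ...) {
  cat("Alpha-cell model parameters\n")
  cat(sprintf("  C_m = %g pF; g_leak = %g nS (V_leak = %g mV); V_K = %g mV\n",
              x$c_m, x$g_leak, x$v_leak, x$v_k))
  cat(sprintf("  g_KATP: %g nS (<= %g mM glucose) -> %g nS (>= %g mM)\n",
              x$g_katp_low, x$glucose_low, x$g_katp_high, x$glucose_high))
  g <- vapply(x$channels, function(ch) ch$g_max, numeric(1))
  cat("  channels (g_max, nS):",
      paste(sprintf("%s %.3g", names(g), g), collapse = ", "), "\n")
  cat(sprintf("  SGLT2: n = %g transporters, Na+ %g/%g mM out/in\n",
              x$sglt2$n_transporters, x$sglt2$na_out, x$sglt2$na_in))
  invisible(x)
}

#' Map extracellular glucose to KATP conductance and SGLT2 glucose
#'
#' Glucose acts twice in the model: through metabolism on the KATP
#' conductance (a two-level map, saturated at `glucose_high`, linearly
#' interpolated below) and directly on the transporter (identity:
#' G_SGLT2 equals extracellular glucose).
#'
#' @param params An [cell_params()] object.
#' @param glucose Extracellular glucose (mM).
#' @return List with `g_katp` (nS) and `g_sglt2` (mM).
#' @export
glucose_map <- function(params, glucose) {
  stopifnot(inherits(params, "acell_params"), glucose >= 0)
  frac <- (glucose - params$glucose_low) /
    (params$glucose_high - params$glucose_low)
  frac <- min(max(frac, 0), 1)
  list(g_katp = params$g_katp_low +
         frac * (params$g_katp_high - params$g_katp_low),
       g_sglt2 = glucose)
}

# flatten one gating spec into the 6-number layout used by the C code
.pack_gate <- function(spec) {
  if (is.null(spec)) return(rep(0, 6))
  c(spec$v_half, spec$slope, spec$tau$floor, spec$tau$peak,
    spec$tau$v_mid, spec$tau$width)
}

#' Pack model parameters for the compiled right-hand side
#'
#' Internal layout documented in src/acell_derivs.c.
#'
#' @param params An [cell_params()] object.
#' @param glucose Extracellular glucose (mM).
#' @param dapagliflozin If `TRUE`, all SGLT2 transporters are blocked
#'   (n forced to 0).
#' @param sglt2_multiplier Scale factor on the transporter count.
#' @return Numeric vector of length 126.
#' @keywords internal
pack_cell_params <- function(params, glucose, dapagliflozin = FALSE,
                             sglt2_multiplier = 1) {
  gm <- glucose_map(params, glucose)
  sg <- params$sglt2
  n_eff <- if (dapagliflozin) 0 else sg$n_transporters * sglt2_multiplier
  chans <- unlist(lapply(params$channels, function(ch) {
    c(ch$g_max, ch$v_rev, ch$activation_exponent,
      if (is.null(ch$activation)) c(0, 1, 1, 0, 0, 1)
      else .pack_gate(ch$activation),
      as.numeric(!is.null(ch$inactivation)),
      if (is.null(ch$inactivation)) c(0, -1, 1, 0, 0, 1)
      else .pack_gate(ch$inactivation))
  }))
  gi <- if (is.null(sg$glucose_in)) -1 else sg$glucose_in
  c(params$c_m, chans,
    gm$g_katp, params$v_k, params$g_leak, params$v_leak,
    n_eff, sg$theta, sg$rtf * 1000, sg$na_out^sg$na_stoichiometry,
    sg$na_in^sg$na_stoichiometry, gm$g_sglt2, gi,
    sg$rates, sg$valences)
}

#' Deterministic initial state
#'
#' Gates at their Boltzmann steady state and SGLT2 occupancies at the
#' kinetic steady state for the given holding potential.
#'
#' @inheritParams pack_cell_params
#' @param v0 Initial membrane potential (mV).
#' @return Named state vector (length 19).
#' @export
initial_state <- function(params, glucose, v0 = -70, dapagliflozin = FALSE) {
  gm <- glucose_map(params, glucose)
  gates <- unlist(lapply(params$channels, function(ch) {
    c(if (is.null(ch$activation)) 0 else boltzmann(v0, ch$activation),
      if (is.null(ch$inactivation)) 0 else boltzmann(v0, ch$inactivation))
  }))
  p <- unclass(sglt2_steady_state(v0, gm$g_sglt2, params$sglt2))
  stats::setNames(c(v0, gates, p),
                  c("v", .acell_gate_names, paste0("p", 1:6)))
}

#' Reference right-hand side of the membrane equation
#'
#' Plain-R assembly of all state derivatives and per-current contributions:
#' \eqn{dV/dt = -(I_{NaV} + I_{CaT} + I_{CaL} + I_{CaPQ} + I_{KA} + I_{Kdr}
#' + I_{KATP} + I_{leak} + I_{SGLT2})/C_m}. The compiled right-hand side in
#' src/ is the one used by [simulate_protocol()]; this function is the
#' readable reference and is tested against it.
#'
#' @param state Named state vector as produced by [initial_state()].
#' @inheritParams pack_cell_params
#' @return List with `derivatives` (named, same layout as `state`) and
#'   `currents` (named pA, outward positive).
#' @export
acell_rhs <- function(state, params, glucose, dapagliflozin = FALSE,
                      sglt2_multiplier = 1) {
  v <- state[[1]]
  gm <- glucose_map(params, glucose)
  d <- numeric(length(state))
  cur <- stats::setNames(numeric(9), .acell_current_names)
  for (i in seq_along(.acell_channel_order)) {
    ch <- params$channels[[i]]
    im <- 2 * i; ih <- 2 * i + 1
    m <- state[[im]]; h <- state[[ih]]
    if (!is.null(ch$activation)) d[im] <- gating_rhs(m, v, ch$activation)
    if (!is.null(ch$inactivation)) d[ih] <- gating_rhs(h, v, ch$inactivation)
    cur[i] <- channel_current(v, ch,
                              m = if (is.null(ch$activation)) 1 else m,
                              h = if (is.null(ch$inactivation)) 1 else h)
  }
  cur["i_katp"] <- gm$g_katp * (v - params$v_k)
  cur["i_leak"] <- params$g_leak * (v - params$v_leak)
  sg <- params$sglt2
  n_eff <- if (dapagliflozin) 0 else sg$n_transporters * sglt2_multiplier
  sg_eff <- sg
  sg_eff$n_transporters <- n_eff
  occ <- state[14:19]
  Q <- sglt2_rate_matrix(v, gm$g_sglt2, sg)
  d[14:19] <- as.vector(Q %*% occ)
  cur["i_sglt2"] <- sglt2_current(occ / sum(occ), v, gm$g_sglt2, sg_eff)
  if (any(!is.finite(cur))) {
    bad <- .acell_current_names[!is.finite(cur)]
    stop("non-finite current in right-hand side: ",
         paste(bad, collapse = ", "))
  }
  d[1] <- -sum(cur) / params$c_m
  list(derivatives = stats::setNames(d, names(state)), currents = cur)
}

#' Simulation protocol
#'
#' Ordered segments of a whole-cell simulation: at each segment boundary the
#' extracellular glucose, the dapagliflozin flag and the transporter-count
#' multiplier change instantaneously.
#'
#' @param glucose Extracellular glucose per segment (mM).
#' @param duration Segment durations (s), positive.
#' @param dapagliflozin Logical per segment; `TRUE` blocks all transporters.
#' @param sglt2_multiplier Scale on the transporter count per segment.
#' @param label Optional segment labels.
#' @return Data frame of class `acell_protocol`.
#' @export
protocol <- function(glucose, duration, dapagliflozin = FALSE,
                     sglt2_multiplier = 1, label = NULL) {
  n <- length(glucose)
  stopifnot(n >= 1, all(duration > 0), all(glucose >= 0))
  if (is.null(label))
    label <- paste0(glucose, "mM", ifelse(rep_len(dapagliflozin, n),
                                          "+dapa", ""))
  out <- data.frame(glucose = glucose,
                    duration = rep_len(duration, n),
                    dapagliflozin = rep_len(dapagliflozin, n),
                    sglt2_multiplier = rep_len(sglt2_multiplier, n),
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("acell_protocol", "data.frame")
  out
}

#' The glucose-step / dapagliflozin protocol
#'
#' Four segments: 1 mM, 6 mM and 11 mM glucose, then 11 mM with simulated
#' dapagliflozin (all transporters blocked, n = 0).
#'
#' @param segment_s Duration of each segment (s).
#' @return An [protocol()] object.
#' @export
figure2_protocol <- function(segment_s = 10) {
  protocol(glucose = c(1, 6, 11, 11),
           duration = segment_s,
           dapagliflozin = c(FALSE, FALSE, FALSE, TRUE),
           label = c("1mM", "6mM", "11mM", "11mM+dapa"))
}

#' Simulate the whole-cell model over a protocol
#'
#' Integrates the membrane ODE system with a stiff solver (the compiled
#' right-hand side, `lsoda` with tight tolerances, an `ode15s` analogue).
#' The initial condition is deterministic ([initial_state()] at -70 mV under
#' the first segment's condition) followed by a discarded burn-in; segment
#' transitions are instantaneous parameter changes with state carried over.
#'
#' @param params An [cell_params()] object.
#' @param proto An [protocol()] object (or data frame with the same columns).
#' @param burn_in_s Burn-in at the first segment's condition (s), discarded.
#' @param sample_khz Output sampling rate (kHz).
#' @param rtol,atol Solver tolerances.
#' @param hmax Maximum solver step (ms).
#' @return An `acell_trace` data frame: `time` (s), `segment`, `glucose`,
#'   `dapagliflozin`, `v` (mV), all gate and occupancy states, and one
#'   column per current (pA, outward positive).
#' @export
simulate_protocol <- function(params, proto, burn_in_s = 5, sample_khz = 2,
                              rtol = 1e-8, atol = 1e-10, hmax = 1) {
  stopifnot(inherits(params, "acell_params"))
  proto <- as.data.frame(proto)
  y <- initial_state(params, proto$glucose[1],
                     dapagliflozin = proto$dapagliflozin[1])
  dt <- 1 / sample_khz
  outnames <- c(.acell_current_names, "j_glc")
  run_segment <- function(y, seg, dur_ms) {
    pv <- pack_cell_params(params, seg$glucose, seg$dapagliflozin,
                           seg$sglt2_multiplier)
    times <- seq(0, dur_ms, by = dt)
    out <- deSolve::ode(y = y, times = times, func = "acell_derivs",
                        parms = pv, dllname = "acellsim",
                        initfunc = "acell_initmod", nout = 10,
                        outnames = outnames, method = "lsoda",
                        rtol = rtol, atol = atol, hmax = hmax)
    if (attr(out, "istate")[1] < 0)
      stop("solver failure in segment ", seg$label,
           "; last state: ", paste(signif(out[nrow(out), 2:20], 6),
                                   collapse = ", "))
    out
  }
  # burn-in under first-segment conditions, discarded
  if (burn_in_s > 0) {
    seg1 <- proto[1, ]
    seg1$sglt2_multiplier <- proto$sglt2_multiplier[1]
    bo <- run_segment(y, seg1, burn_in_s * 1000)
    y <- bo[nrow(bo), 1 + seq_along(y)]
    names(y) <- names(initial_state(params, proto$glucose[1]))
  }
  t0 <- 0
  pieces <- vector("list", nrow(proto))
  for (s in seq_len(nrow(proto))) {
    seg <- proto[s, ]
    out <- run_segment(y, seg, seg$duration * 1000)
    y <- out[nrow(out), 1 + seq_len(19)]
    names(y) <- names(initial_state(params, seg$glucose))
    df <- as.data.frame(out)
    drop_first <- if (s == 1) FALSE else c(TRUE, rep(FALSE, nrow(df) - 1))
    df <- df[!drop_first, , drop = FALSE]
    df$time <- (t0 + df$time) / 1000
    df$segment <- seg$label
    df$glucose <- seg$glucose
    df$dapagliflozin <- seg$dapagliflozin
    pieces[[s]] <- df
    t0 <- t0 + seg$duration * 1000
  }
  tr <- do.call(rbind, pieces)
  names(tr)[2] <- "v"
  if (anyNA(tr$v) || any(!is.finite(tr$v)))
    stop("non-finite membrane potential in simulation output")
  rownames(tr) <- NULL
  attr(tr, "c_m") <- params$c_m
  attr(tr, "sample_khz") <- sample_khz
  class(tr) <- c("acell_trace", "data.frame")
  tr
}

#' @export
print.acell_trace <- function(x, ...) {
  cat(sprintf("Alpha-cell trace: %.3g s, %d samples, segments: %s\n",
              max(x$time) - min(x$time), nrow(x),
              paste(unique(x$segment), collapse = ", ")))
  cat(sprintf("  V range [%.1f, %.1f] mV\n", min(x$v), max(x$v)))
  invisible(x)
}

#' @export
plot.acell_trace <- function(x, ...) {
  graphics::plot(x$time, x$v, type = "l", xlab = "time (s)",
                 ylab = "V (mV)", ...)
  bounds <- x$time[c(which(diff(as.integer(factor(x$segment, levels = unique(x$segment)))) != 0))]
  graphics::abline(v = bounds, lty = 3, col = "grey50")
  invisible(x)
}

#' Robustness check: transporter over-expression
#'
#' Simulates the low-glucose (1 mM) condition with the transporter count
#' scaled by `multiplier` and classifies the output as AP-like or not by
#' action-potential detection: AP-like requires at least `min_aps` detected
#' spikes with mean amplitude of at least `min_amplitude` mV.
#'
#' @param params An [cell_params()] object.
#' @param multiplier Scale on the transporter count (> 0 allowed; 0 behaves
#'   as dapagliflozin).
#' @param duration_s Analysed simulation length (s).
#' @param min_aps,min_amplitude Classification thresholds.
#' @return List with `classification` ("AP-like" or "not AP-like"),
#'   `features` (an [detect_aps()] result) and the trace.
#' @export
overexpression_check <- function(params, multiplier, duration_s = 10,
                                 min_aps = 3, min_amplitude = 15) {
  stopifnot(multiplier >= 0)
  pr <- protocol(glucose = 1, duration = duration_s,
                 sglt2_multiplier = multiplier,
                 label = sprintf("1mM x%g SGLT2", multiplier))
  tr <- simulate_protocol(params, pr)
  f <- detect_aps(tr)
  ap_like <- f$count >= min_aps && f$mean_amplitude >= min_amplitude
  list(classification = if (ap_like) "AP-like" else "not AP-like",
       features = f, trace = tr)
}
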