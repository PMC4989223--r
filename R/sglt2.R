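## Six-state alternating-access model of electrogenic Na+/glucose co-transport
## (SGLT2).  States, in cycle order:
##   1 outward-facing empty carrier
##   2 outward-facing, Na+ bound
##   3 outward-facing, Na+ and glucose bound
##   4 inward-facing, Na+ and glucose bound
##   5 inward-facing, Na+ bound
##   6 inward-facing empty carrier
## Forward (clockwise) direction 1->2->3->4->5->6->1 carries na_stoichiometry
## Na+ ions and one glucose into the cell per cycle; Na+ binding and release
## are treated as concerted, so binding rates scale with [Na]^stoichiometry.

.sglt2_rate_names <- c("k12", "k21", "k23", "k32", "k34", "k43",
                       "k45", "k54", "k56", "k65", "k61", "k16")
.sglt2_valence_names <- c("z12", "z23", "z34", "z45", "z56", "z61")

# e (C) converted so that (events/ms) * n -> pA
.E_PA_PER_MS <- 1.602176634e-4
# molecules/ms -> uM/s for a volume in pL: 1e3/(N_A * 1e-12 * 1e-6)
.FLUX_UM_S <- 1e3 / (6.02214076e23 * 1e-12 * 1e-6)

#' Parameters of the six-state SGLT2 co-transport model
#'
#' Zero-voltage rate constants are given per transition of the alternating-
#' access cycle; ligand-binding rates (`k12`, `k65` for Na+; `k23`, `k54` for
#' glucose) are second order, per mM per ms, and are multiplied by the
#' relevant concentration when the rate matrix is built. Apparent valences
#' `z12 ... z61` give the charge (inward positive) moved across the membrane
#' field by each forward transition; charged transitions are scaled by
#' \eqn{\exp(\mp z\,\theta\,FV/RT)} (forward) and \eqn{\exp(\pm z(1-\theta)FV/RT)}
#' (backward), so `theta = 0.5` reproduces the symmetric F V/(2RT) split and
#' `theta = 1` puts the whole voltage dependence on the inward-directed rate.
#' The ratio of forward to backward rates, and hence microscopic
#' reversibility, is independent of `theta`.
#'
#' By default `k16` is derived from the other eleven rates so that the
#' product of intrinsic clockwise rates equals the product of
#' counter-clockwise rates; together with the voltage and concentration
#' factors this enforces microscopic reversibility: the cycle-product ratio
#' equals \eqn{([Na]_o/[Na]_i)^{st}\,([G]_o/[G]_i)\,e^{-z_{tot}FV/RT}} with
#' \eqn{z_{tot}} the summed valences and st the Na+ stoichiometry.
#'
#' @param rates Named numeric vector or list with entries `k12, k21, k23,
#'   k32, k34, k43, k45, k54, k56, k65, k61` and optionally `k16` (derived
#'   from detailed balance when omitted). Units per ms (binding rates per mM
#'   per ms). All positive.
#' @param valences Named numeric vector/list `z12, z23, z34, z45, z56, z61`
#'   (dimensionless). Their sum is the net charge moved per forward cycle.
#' @param theta Voltage-split asymmetry in \[0, 1\]; see Details.
#' @param n_transporters Number of functional transporters n (>= 0);
#'   dapagliflozin block is modelled as n = 0.
#' @param na_out,na_in Extra-/intracellular Na+ (mM).
#' @param glucose_in Intracellular glucose (mM), or `NULL` to tie it to the
#'   extracellular value (glucose equilibrated across the membrane by GLUT1).
#' @param na_stoichiometry Na+:glucose coupling ratio; the packaged sets use
#'   2 (the Parent-type cycle), and the summed valences should equal it.
#' @param temperature_c Temperature (deg C) used for RT/F.
#' @return An object of class `sglt2_params`.
#' @export
sglt2_params <- function(rates, valences = c(z12 = 0.3, z23 = 0, z34 = 0,
                                             z45 = 0, z56 = 0, z61 = 0.7),
                         theta = 1, n_transporters = 0,
                         na_out = 140, na_in = 10, glucose_in = NULL,
                         na_stoichiometry = 2L, temperature_c = 37) {
  rates <- unlist(rates)
  need <- setdiff(.sglt2_rate_names, "k16")
  if (!all(need %in% names(rates)))
    stop("missing rate constants: ", paste(setdiff(need, names(rates)), collapse = ", "))
  if (!("k16" %in% names(rates))) {
    cw <- prod(rates[c("k12", "k23", "k34", "k45", "k56", "k61")])
    ccw <- prod(rates[c("k21", "k32", "k43", "k54", "k65")])
    rates <- c(rates, k16 = unname(cw / ccw))
  }
  rates <- rates[.sglt2_rate_names]
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants must be positive and finite")
  valences <- unlist(valences)[.sglt2_valence_names]
  if (anyNA(valences)) stop("valences must name z12, z23, z34, z45, z56, z61")
  stopifnot(theta >= 0, theta <= 1, n_transporters >= 0,
            na_out >= 0, na_in >= 0)
  if (!is.null(glucose_in) && glucose_in < 0)
    stop("glucose_in must be >= 0")
  structure(list(rates = rates, valences = valences, theta = theta,
                 n_transporters = n_transporters,
                 na_out = na_out, na_in = na_in, glucose_in = glucose_in,
                 na_stoichiometry = as.integer(na_stoichiometry),
                 rtf = 8.31446 * (273.15 + temperature_c) / 96485.3),
            class = "sglt2_params")
}

# forward/backward rates of the six cycle transitions at voltage v (mV)
sglt2_transition_rates <- function(v, glucose_out, params) {
  stopifnot(inherits(params, "sglt2_params"))
  if (glucose_out < 0) stop("glucose_out must be >= 0")
  k <- params$rates
  z <- params$valences
  gi <- if (is.null(params$glucose_in)) glucose_out else params$glucose_in
  u <- v / (params$rtf * 1000) # rtf stored in V; voltages in mV
  st <- params$na_stoichiometry
  f <- c(k[["k12"]] * params$na_out^st, k[["k23"]] * glucose_out, k[["k34"]],
         k[["k45"]], k[["k56"]], k[["k61"]])
  b <- c(k[["k21"]], k[["k32"]], k[["k43"]], k[["k54"]] * gi,
         k[["k65"]] * params$na_in^st, k[["k16"]])
  vf <- exp(-z * params$theta * u)
  vb <- exp(z * (1 - params$theta) * u)
  list(forward = unname(f * vf), backward = unname(b * vb))
}

#' Transition-rate matrix of the SGLT2 cycle
#'
#' Builds the 6x6 generator Q of the occupancy master equation
#' \eqn{dp/dt = Q p}: `Q[i, j]` is the rate from state j to state i for
#' i != j, and columns sum to zero.
#'
#' @param v Membrane potential (mV).
#' @param glucose_out Extracellular glucose seen by the transporter (mM).
#' @param params An [sglt2_params()] object.
#' @return 6x6 numeric matrix (per ms).
#' @export
sglt2_rate_matrix <- function(v, glucose_out, params) {
  r <- sglt2_transition_rates(v, glucose_out, params)
  Q <- matrix(0, 6, 6)
  for (s in 1:6) {
    to <- s %% 6 + 1
    Q[to, s] <- Q[to, s] + r$forward[s]
    Q[s, to] <- Q[s, to] + r$backward[s]
  }
  diag(Q) <- -colSums(Q)
  Q
}

#' Steady-state occupancy of the SGLT2 cycle
#'
#' Normalized null-space vector of the rate matrix at fixed voltage and
#' concentrations.
#'
#' @inheritParams sglt2_rate_matrix
#' @return Numeric vector of 6 non-negative occupancies summing to 1,
#'   class `sglt2_state`.
#' @export
sglt2_steady_state <- function(v, glucose_out, params) {
  Q <- sglt2_rate_matrix(v, glucose_out, params)
  A <- rbind(Q[-6, , drop = FALSE], rep(1, 6))
  p <- tryCatch(solve(A, c(rep(0, 5), 1)),
                error = function(e) stop("degenerate SGLT2 rate matrix: ",
                                         conditionMessage(e)))
  if (any(p < -1e-9)) stop("degenerate SGLT2 rate matrix: negative occupancy")
  p <- pmax(p, 0)
  structure(p / sum(p), class = "sglt2_state")
}

#' Instantaneous SGLT2 membrane current
#'
#' Sum over charged transitions of valence times net forward flux, scaled by
#' the elementary charge and the transporter count; outward positive, so
#' forward (inward-translocating) cycling gives a negative current.
#'
#' @param state Occupancy vector (6 fractions summing to 1).
#' @inheritParams sglt2_rate_matrix
#' @return Current in pA (outward positive).
#' @export
sglt2_current <- function(state, v, glucose_out, params) {
  state <- unclass(state)
  stopifnot(length(state) == 6, all(state >= 0),
            abs(sum(state) - 1) < 1e-6)
  r <- sglt2_transition_rates(v, glucose_out, params)
  to <- c(2:6, 1)
  J <- r$forward * state - r$backward * state[to]
  -.E_PA_PER_MS * params$n_transporters * sum(params$valences * J)
}

#' SGLT2-mediated glucose flux
#'
#' Net inward flux through the sugar-loaded translocation step (3 -> 4),
#' scaled to a whole-cell concentration change per second.
#'
#' @param state Occupancy vector (6 fractions summing to 1).
#' @inheritParams sglt2_rate_matrix
#' @param cell_volume Cell volume in pL.
#' @return Glucose influx in uM/s (inward positive).
#' @export
sglt2_glucose_flux <- function(state, v, glucose_out, params,
                               cell_volume = 0.8) {
  if (cell_volume <= 0) stop("cell_volume must be > 0")
  state <- unclass(state)
  r <- sglt2_transition_rates(v, glucose_out, params)
  j34 <- r$forward[3] * state[3] - r$backward[3] * state[4]
  params$n_transporters * j34 * .FLUX_UM_S / cell_volume
}

# occupancy ODE under clamped voltage, dense output; linear system dp/dt = Qp
sglt2_integrate_clamp <- function(p0, v, glucose_out, params, duration,
                                  dt = 0.05) {
  Q <- sglt2_rate_matrix(v, glucose_out, params)
  times <- seq(0, duration, by = dt)
  out <- deSolve::ode(y = p0, times = times,
                      func = function(t, y, parms) list(parms %*% y),
                      parms = Q, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  unname(out[, -1, drop = FALSE])
}

#' Voltage-clamp simulation of the SGLT2 current
#'
#' Integrates the occupancy master equation under a piecewise-constant
#' voltage protocol, starting from the steady state of the first segment,
#' and decomposes the current in each subsequent segment into a sustained
#' (plateau) component and a transient charge movement.
#'
#' The plateau is detected where |dI/dt| stays below `plateau_tol` for
#' `plateau_ms`; the transient charge is \eqn{\int (I - I_{sustained})\,dt}
#' over the segment.
#'
#' @param protocol Data frame or list of segments with columns/fields
#'   `duration` (ms, positive) and `v` (mV); the first segment is the
#'   holding potential.
#' @inheritParams sglt2_rate_matrix
#' @param dt Output sampling interval (ms).
#' @param plateau_tol Plateau detection tolerance (pA/ms).
#' @param plateau_ms Time |dI/dt| must stay below tolerance (ms).
#' @return An object of class `sglt2_clamp`: list with `trace` (data frame:
#'   time, v, i_sglt2, p1..p6) and `segments` (data frame: v, duration,
#'   sustained_pa, transient_pc, converged).
#' @export
sglt2_voltage_clamp <- function(protocol, glucose_out, params, dt = 0.05,
                                plateau_tol = 1e-4, plateau_ms = 5) {
  protocol <- as.data.frame(protocol)
  stopifnot(all(c("duration", "v") %in% names(protocol)),
            all(protocol$duration > 0))
  p <- unclass(sglt2_steady_state(protocol$v[1], glucose_out, params))
  t0 <- 0
  trace <- NULL
  seginfo <- NULL
  for (s in seq_len(nrow(protocol))) {
    v <- protocol$v[s]
    dur <- protocol$duration[s]
    occ <- sglt2_integrate_clamp(p, v, glucose_out, params, dur, dt)
    tt <- seq(0, dur, by = dt)
    I <- apply(occ, 1, sglt2_current, v = v, glucose_out = glucose_out,
               params = params)
    # plateau detection on the sampled derivative
    dIdt <- c(diff(I) / dt, 0)
    need <- max(1L, ceiling(plateau_ms / dt))
    calm <- abs(dIdt) < plateau_tol
    run <- rle(calm)
    idx <- NULL
    pos <- cumsum(run$lengths)
    ok <- which(run$values & run$lengths >= need)
    converged <- length(ok) > 0
    i_sus <- I[length(I)]
    if (converged) {
      first <- ok[1]
      start <- if (first == 1) 1L else pos[first - 1] + 1L
      i_sus <- mean(I[seq(start + need - 1L, pos[first])])
    }
    q_trans <- sum((I - i_sus)[-length(I)] + (I - i_sus)[-1]) / 2 * dt / 1000
    trace <- rbind(trace,
                   data.frame(time = t0 + tt, v = v, i_sglt2 = I,
                              p1 = occ[, 1], p2 = occ[, 2], p3 = occ[, 3],
                              p4 = occ[, 4], p5 = occ[, 5], p6 = occ[, 6]))
    seginfo <- rbind(seginfo,
                     data.frame(v = v, duration = dur, sustained_pa = i_sus,
                                transient_pc = q_trans, converged = converged))
    p <- occ[nrow(occ), ]
    t0 <- t0 + dur
  }
  structure(list(trace = trace, segments = seginfo,
                 glucose_out = glucose_out),
            class = "sglt2_clamp")
}

#' @export
print.sglt2_clamp <- function(x, ...) {
  cat("SGLT2 voltage clamp at", x$glucose_out, "mM external glucose\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}
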