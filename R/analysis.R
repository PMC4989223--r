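#' Detect action potentials in a voltage trace
#'
#' Action potentials are upward crossings of a voltage threshold whose
#' peak-minus-preceding-trough excursion (amplitude) reaches
#' `min_prominence`. The threshold defaults to the trace median plus 10 mV,
#' which makes detection invariant to adding a constant to the trace.
#'
#' @param trace An `acell_trace` (or any data frame with `time` in s and
#'   `v` in mV), or a numeric voltage vector (then supply `time`).
#' @param time Time vector (s), only when `trace` is a bare numeric vector.
#' @param threshold Detection threshold (mV); default `median(v) + 10`.
#' @param min_prominence Minimum peak-minus-trough excursion (mV).
#' @return An object of class `ap_features`: `count`, per-AP `peak_v`,
#'   `trough_v`, `amplitude` (peak minus preceding trough), `peak_time`,
#'   `frequency` (Hz over the analysed window), `mean_amplitude`,
#'   `mean_peak_v`, `mean_trough_v`, `duration`, `low_confidence`.
#' @export
detect_aps <- function(trace, time = NULL, threshold = NULL,
                       min_prominence = 5) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    v <- trace
    if (is.null(time)) stop("supply a time vector with a bare voltage vector")
  } else {
    trace <- as.data.frame(trace)
    stopifnot(all(c("time", "v") %in% names(trace)))
    v <- trace$v
    time <- trace$time
  }
  stopifnot(length(v) == length(time), length(v) > 0)
  if (is.null(threshold) || is.na(threshold))
    threshold <- stats::median(v) + 10
  dur <- max(time) - min(time)

  above <- v >= threshold
  up <- which(diff(above) == 1) + 1L
  down <- which(diff(above) == -1) + 1L

  peaks <- troughs <- amps <- ptime <- numeric(0)
  prev_end <- 1L
  for (u in up) {
    d <- down[down > u]
    d <- if (length(d)) d[1] else length(v)
    seg <- u:d
    pk <- which.max(v[seg]) + u - 1L
    tr_seg <- prev_end:u
    trough <- min(v[tr_seg])
    amp <- v[pk] - trough
    if (amp >= min_prominence) {
      peaks <- c(peaks, v[pk])
      troughs <- c(troughs, trough)
      amps <- c(amps, amp)
      ptime <- c(ptime, time[pk])
    }
    prev_end <- d
  }
  count <- length(peaks)
  low_confidence <- FALSE
  if (count >= 1 && count < 2) {
    low_confidence <- TRUE
    warning("analysis window shorter than two AP periods; ",
            "frequency is low-confidence")
  }
  structure(list(count = count, peak_v = peaks, trough_v = troughs,
                 amplitude = amps, peak_time = ptime,
                 frequency = if (dur > 0) count / dur else 0,
                 mean_amplitude = if (count) mean(amps) else 0,
                 mean_peak_v = if (count) mean(peaks) else NA_real_,
                 mean_trough_v = if (count) mean(troughs) else NA_real_,
                 duration = dur, threshold = threshold,
                 low_confidence = low_confidence),
            class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf("%d action potentials in %.3g s (%.3g Hz)\n",
              x$count, x$duration, x$frequency))
  if (x$count)
    cat(sprintf("  mean amplitude %.2f mV (peak %.2f mV, trough %.2f mV)\n",
                x$mean_amplitude, x$mean_peak_v, x$mean_trough_v))
  invisible(x)
}

# whole-cell steady-state clamp current at voltage v (all gates and SGLT2
# occupancies fully relaxed), by component
clamp_steady_current <- function(params, glucose, v,
                                 component = c("all", "sglt2"),
                                 dapagliflozin = FALSE) {
  component <- match.arg(component)
  gm <- glucose_map(params, glucose)
  sg <- params$sglt2
  if (dapagliflozin) sg$n_transporters <- 0
  ss <- sglt2_steady_state(v, gm$g_sglt2, sg)
  i_sglt2 <- sglt2_current(ss, v, gm$g_sglt2, sg)
  if (component == "sglt2") return(i_sglt2)
  i_ch <- sum(vapply(params$channels, channel_current_ss, numeric(1), v = v))
  i_ch + katp_leak_current(v, gm$g_katp, params$g_leak,
                           params$v_k, params$v_leak) + i_sglt2
}

#' Background (resting) conductance from small voltage steps
#'
#' Slope conductance \eqn{\Delta I_{steady} / \Delta V} between clamped
#' steady states at `v_hold` and `v_hold + dv`, for the full current or the
#' SGLT2 component alone, as in experimental resting-conductance
#' measurements with small depolarizing steps.
#'
#' @param params An [cell_params()] object.
#' @param glucose Extracellular glucose (mM).
#' @param v_hold Holding potential (mV).
#' @param dv Step size (mV).
#' @param component `"all"` (every conductance) or `"sglt2"` (transporter
#'   current only).
#' @param dapagliflozin If `TRUE`, transporters are blocked.
#' @return Conductance in pS.
#' @export
background_conductance <- function(params, glucose, v_hold = -70, dv = 10,
                                   component = c("all", "sglt2"),
                                   dapagliflozin = FALSE) {
  component <- match.arg(component)
  i0 <- clamp_steady_current(params, glucose, v_hold, component,
                             dapagliflozin)
  i1 <- clamp_steady_current(params, glucose, v_hold + dv, component,
                             dapagliflozin)
  if (!is.finite(i0) || !is.finite(i1))
    stop("clamp steady state did not converge")
  (i1 - i0) / dv * 1000 # nS -> pS
}

#' Steady-state glucose flux balance
#'
#' At steady state the influx balances the outflux plus consumption,
#' \eqn{J_{in} + J_{SGLT2} = (k_{out} + k_{consumption}) G_i}. Given the
#' GLUT1 influx, total consumption and SGLT2 influx (all uM/s), reports the
#' outward GLUT1 flux, the SGLT2 share of total uptake, and the fractional
#' drop in intracellular glucose and consumption when SGLT2 is blocked
#' (linear-consumption assumption, so both equal the SGLT2 share).
#'
#' @param j_in GLUT1 glucose influx (uM/s).
#' @param j_consumption Glucose consumption (uM/s).
#' @param j_sglt2 SGLT2-mediated glucose influx (uM/s).
#' @return List with `glut1_outward` (uM/s), `sglt2_share` (fraction),
#'   `sglt2_share_pct`, `delta_gi_pct` and `delta_consumption_pct` (%
#'   decrease on SGLT2 block).
#' @export
flux_balance_analysis <- function(j_in, j_consumption, j_sglt2) {
  stopifnot(j_in >= 0, j_consumption >= 0, j_sglt2 >= 0)
  if (j_consumption > j_in + j_sglt2)
    stop("infeasible steady state: consumption exceeds total influx")
  outward <- j_in + j_sglt2 - j_consumption
  share <- if (j_in + j_sglt2 > 0) j_sglt2 / (j_in + j_sglt2) else 0
  list(glut1_outward = outward,
       sglt2_share = share,
       sglt2_share_pct = 100 * share,
       delta_gi_pct = 100 * share,
       delta_consumption_pct = 100 * share)
}

#' Free drug concentration after plasma protein binding
#'
#' @param total Total drug concentration (nM).
#' @param protein_bound_fraction Fraction bound to plasma protein in \[0, 1\].
#' @return Free concentration (nM): `total * (1 - protein_bound_fraction)`.
#' @examples
#' free_drug_concentration(c(24, 240), 0.93) # therapeutic dapagliflozin range
#' @export
free_drug_concentration <- function(total, protein_bound_fraction) {
  stopifnot(all(total >= 0),
            protein_bound_fraction >= 0, protein_bound_fraction <= 1)
  total * (1 - protein_bound_fraction)
}
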