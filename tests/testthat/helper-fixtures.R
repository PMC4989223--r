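# Small generic fixtures used across test files.  The kinetic values here are
# deliberately simple round numbers (not the packaged calibrated set) so that
# analytic oracles stay tractable.

# a symmetric, detailed-balance-consistent transporter (k16 derived)
test_sglt2 <- function(n = 1e6, theta = 1, na_out = 140, na_in = 10,
                       glucose_in = NULL, stoich = 2) {
  sglt2_params(rates = c(k12 = 1e-4, k21 = 0.5, k23 = 0.3, k32 = 2,
                         k34 = 0.01, k43 = 0.01, k45 = 0.4, k54 = 0.02,
                         k56 = 0.4, k65 = 1e-3, k61 = 0.05),
               valences = c(z12 = 0.2, z23 = 0.4, z34 = 0.8, z45 = 0.1,
                            z56 = 0, z61 = 0.5),
               theta = theta, n_transporters = n, na_out = na_out,
               na_in = na_in, glucose_in = glucose_in,
               na_stoichiometry = stoich)
}

# random valid transporter parameters for property tests
random_sglt2 <- function() {
  r <- stats::runif(11, 0.01, 2)
  names(r) <- c("k12", "k21", "k23", "k32", "k34", "k43", "k45", "k54",
                "k56", "k65", "k61")
  r["k12"] <- stats::runif(1, 1e-5, 1e-3)
  z <- stats::runif(4, 0, 0.8)
  sglt2_params(rates = r,
               valences = c(z12 = z[1], z23 = z[2], z34 = z[3], z45 = 0,
                            z56 = 0, z61 = z[4]),
               theta = stats::runif(1), n_transporters = 1e6,
               na_out = stats::runif(1, 100, 150),
               na_in = stats::runif(1, 5, 20),
               glucose_in = stats::runif(1, 0.5, 10))
}

# minimal ohmic-only cell (all gated conductances and transporters silent)
ohmic_cell <- function(g_katp = 0.15, g_leak = 0.05, v_k = -75, v_leak = -20) {
  ch <- function(nm) channel_params(nm, g_max = 0, v_rev = 0,
                                    activation = gating_spec(-30, 5, 1))
  chans <- lapply(c("NaV", "CaT", "CaL", "CaPQ", "KA", "Kdr"), ch)
  names(chans) <- c("NaV", "CaT", "CaL", "CaPQ", "KA", "Kdr")
  cell_params(channels = chans, sglt2 = test_sglt2(n = 0),
              g_katp_low = g_katp, g_katp_high = g_katp,
              g_leak = g_leak, v_k = v_k, v_leak = v_leak)
}

# synthetic voltage trace with triangular spikes of known geometry
synthetic_spike_train <- function(n_spikes = 7, duration = 1, base = -50,
                                  height = 40, dt = 5e-4, width = 0.01) {
  t <- seq(0, duration, by = dt)
  v <- rep(base, length(t))
  centers <- seq(0.5, n_spikes - 0.5, length.out = n_spikes) * duration / n_spikes
  for (ct in centers) {
    idx <- abs(t - ct) <= width / 2
    v[idx] <- base + height * (1 - abs(t[idx] - ct) / (width / 2))
  }
  data.frame(time = t, v = v)
}
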