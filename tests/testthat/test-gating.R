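test_that("Boltzmann steady state matches its closed form and limits", {
  act <- gating_spec(v_half = -30, slope = 5)
  expect_equal(boltzmann(-30, act), 0.5)
  expect_equal(boltzmann(-25, act), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(boltzmann(100, act), 1, tolerance = 1e-9)
  expect_lt(boltzmann(-150, act), 1e-9)
  # inactivation convention: negative slope gives a decreasing curve
  inact <- gating_spec(v_half = -50, slope = -6)
  expect_gt(boltzmann(-70, inact), boltzmann(-30, inact))
  # monotone over a grid, bounded in (0, 1)
  v <- seq(-150, 100, by = 1)
  x <- boltzmann(v, act)
  expect_true(all(diff(x) > 0))
  expect_true(all(x > 0 & x < 1))
  expect_error(boltzmann(NaN, act), "finite")
  expect_error(boltzmann(Inf, act), "finite")
  expect_error(gating_spec(-30, 0), "non-zero")
})

test_that("gating relaxation has the right fixed point, rate and time course", {
  sp <- gating_spec(-30, 5, tau = 2)
  xinf <- boltzmann(-20, sp)
  expect_equal(gating_rhs(xinf, -20, sp), 0)
  # x = 0 with x_inf driven to ~1 at very depolarized v, tau = 2 ms -> 0.5/ms
  expect_equal(gating_rhs(0, 100, sp), 0.5, tolerance = 1e-6)
  # integrated solution relaxes exponentially with time constant tau
  v0 <- -25
  sol <- deSolve::ode(y = c(x = 0), times = seq(0, 10, 0.1),
                      func = function(t, y, p) list(gating_rhs(y, v0, sp)))
  analytic <- boltzmann(v0, sp) * (1 - exp(-sol[, "time"] / 2))
  expect_equal(unname(sol[, "x"]), analytic, tolerance = 1e-6)
})

test_that("voltage-dependent time constants are positive and bell-shaped", {
  sp <- gating_spec(-40, -5, tau = list(floor = 1, peak = 60, v_mid = -45,
                                        width = 20))
  v <- seq(-150, 100, by = 0.5)
  tau <- gating_tau(v, sp)
  expect_true(all(tau > 0))
  expect_equal(v[which.max(tau)], -45)
  expect_equal(max(tau), 61)
  expect_error(gating_spec(-40, -5, tau = list(floor = -1, peak = 6,
                                               v_mid = 0, width = 10)))
})

test_that("HH current obeys ohmic arithmetic and gate conventions", {
  ch <- channel_params("NaV", g_max = 1, v_rev = -75,
                       activation = gating_spec(-30, 5))
  expect_equal(channel_current(-70, ch, m = 1), 5)
  expect_equal(channel_current(-75, ch, m = 0.4), 0)
  ch0 <- channel_params("CaL", g_max = 0, v_rev = 65,
                        activation = gating_spec(-20, 5))
  expect_equal(channel_current(seq(-100, 50, 10), ch0, m = 0.5), rep(0, 16))
  # p exponent and absent gates
  chp <- channel_params("Kdr", g_max = 2, v_rev = -75,
                        activation = gating_spec(-20, 7),
                        activation_exponent = 4)
  expect_equal(channel_current(-25, chp, m = 0.5), 2 * 0.5^4 * 50)
  expect_error(channel_params("X", g_max = -1, v_rev = 0), "g_max")
})

test_that("KATP and leak currents are ohmic and linear in conductance", {
  expect_equal(katp_leak_current(-70, 0.15, 0, v_k = -75, v_leak = -20), 0.75)
  expect_equal(katp_leak_current(-75, 0.2, 0.3, v_k = -75, v_leak = -75), 0)
  i1 <- katp_leak_current(-50, 0.1, 0.02, -75, -20)
  i2 <- katp_leak_current(-50, 0.2, 0.02, -75, -20)
  expect_equal(i2 - i1, 0.1 * 25)
  expect_error(katp_leak_current(-50, -0.1, 0, -75, -20))
})

test_that("every packaged channel current is zero at, and changes sign across, its reversal", {
  p <- acell_default_params()
  for (ch in p$channels) {
    expect_equal(channel_current_ss(ch$v_rev, ch), 0, info = ch$name)
    eps <- 0.5
    below <- channel_current_ss(ch$v_rev - eps, ch)
    above <- channel_current_ss(ch$v_rev + eps, ch)
    expect_lt(below, 0)
    expect_gt(above, 0)
  }
})

test_that("inactivating currents show a window-current extremum", {
  p <- acell_default_params()
  v <- seq(-150, 100, by = 0.25)
  for (nm in c("NaV", "CaT", "CaL", "CaPQ")) {
    iv <- channel_current_ss(v, p$channels[[nm]])
    interior <- which.min(iv) # inward currents: most negative point
    expect_gt(interior, 1)
    expect_lt(interior, length(v))
    # non-monotone: current magnitude rises then falls
    expect_gt(max(abs(iv[seq_len(interior)])), abs(iv[1]))
    expect_gt(max(abs(iv)), abs(iv[length(v)]) * 0) # guard: finite values
    expect_true(all(is.finite(iv)))
  }
})

test_that("ohmic-only cell has a unique resting potential between V_K and V_leak", {
  p <- ohmic_cell(g_katp = 0.15, g_leak = 0.05, v_k = -75, v_leak = -20)
  iv <- function(v) vapply(v, function(vv)
    acellsim:::clamp_steady_current(p, glucose = 1, v = vv), numeric(1))
  root <- stats::uniroot(iv, c(-75, -20), tol = 1e-10)$root
  # brute-force oracle: sign change count over a fine grid
  v <- seq(-120, 40, by = 0.05)
  signs <- sign(iv(v))
  signs <- signs[signs != 0] # the grid may hit the root exactly
  expect_equal(sum(diff(signs) != 0), 1)
  expect_gt(root, -75)
  expect_lt(root, -20)
  # analytic conductance-weighted mean
  expect_equal(root, (0.15 * -75 + 0.05 * -20) / 0.2, tolerance = 1e-6)
})
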