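test_that("rate matrix is a proper generator with mass-action glucose entry", {
  sg <- test_sglt2()
  Q <- sglt2_rate_matrix(-50, 5, sg)
  expect_equal(colSums(Q), rep(0, 6), tolerance = 1e-12)
  off <- Q; diag(off) <- 0
  expect_true(all(off >= 0))
  # zero external glucose silences the outside sugar-binding transition
  Q0 <- sglt2_rate_matrix(-50, 0, test_sglt2(glucose_in = 0))
  expect_equal(Q0[3, 2], 0)
  # a zero-valence transition is voltage independent
  r1 <- acellsim:::sglt2_transition_rates(-80, 5, sg)
  r2 <- acellsim:::sglt2_transition_rates(20, 5, sg)
  expect_equal(r1$forward[5], r2$forward[5]) # z56 = 0
  expect_error(sglt2_rate_matrix(-50, -1, sg), "glucose")
})

test_that("cycle products obey microscopic reversibility at any voltage", {
  set.seed(42)
  for (i in 1:25) {
    sg <- random_sglt2()
    v <- stats::runif(1, -90, 30)
    G <- stats::runif(1, 0.1, 15)
    r <- acellsim:::sglt2_transition_rates(v, G, sg)
    lhs <- prod(r$forward) / prod(r$backward)
    u <- v / (sg$rtf * 1000)
    rhs <- (sg$na_out / sg$na_in)^sg$na_stoichiometry *
      (G / sg$glucose_in) * exp(-sum(sg$valences) * u)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("steady state equals the long-time ODE solution and is scale invariant", {
  set.seed(7)
  for (i in 1:100) {
    sg <- random_sglt2()
    v <- stats::runif(1, -80, 20)
    G <- stats::runif(1, 0.2, 12)
    ss <- unclass(sglt2_steady_state(v, G, sg))
    expect_true(all(ss >= 0))
    expect_equal(sum(ss), 1, tolerance = 1e-12)
    # oracle: integrate dp/dt = Qp from a lopsided start for a long time
    Q <- sglt2_rate_matrix(v, G, sg)
    p0 <- c(1, 0, 0, 0, 0, 0)
    tmax <- 50 / min(abs(Re(eigen(Q)$values[abs(Re(eigen(Q)$values)) > 1e-12])))
    sol <- deSolve::ode(y = p0, times = c(0, tmax),
                        func = function(t, y, p) list(p %*% y), parms = Q,
                        rtol = 1e-11, atol = 1e-13)
    expect_equal(unname(sol[2, -1]), ss, tolerance = 1e-7)
    # invariance under common rescaling of all rates
    sg2 <- sg
    sg2$rates <- sg$rates * 3.7
    expect_equal(unclass(sglt2_steady_state(v, G, sg2)), ss,
                 tolerance = 1e-10)
  }
})

test_that("thermodynamic equilibrium gives detailed balance, zero current and zero flux", {
  # balanced composition: no Na+ gradient, no glucose gradient, V = 0
  sg <- test_sglt2(na_out = 20, na_in = 20, glucose_in = 3)
  ss <- sglt2_steady_state(0, 3, sg)
  r <- acellsim:::sglt2_transition_rates(0, 3, sg)
  to <- c(2:6, 1)
  J <- r$forward * unclass(ss) - r$backward * unclass(ss)[to]
  expect_equal(J, rep(0, 6), tolerance = 1e-12)
  expect_equal(sglt2_current(ss, 0, 3, sg), 0, tolerance = 1e-10)
  expect_equal(sglt2_glucose_flux(ss, 0, 3, sg), 0, tolerance = 1e-10)
})

test_that("transporter current follows the coupled cycle", {
  sg <- test_sglt2()
  ss <- sglt2_steady_state(-60, 5, sg)
  # blocked transporters carry nothing
  sg0 <- test_sglt2(n = 0)
  expect_equal(sglt2_current(ss, -60, 5, sg0), 0)
  expect_equal(sglt2_glucose_flux(ss, -60, 5, sg0), 0)
  # physiological gradient: sustained current is inward, flux is inward
  i <- sglt2_current(ss, -60, 5, sg)
  f <- sglt2_glucose_flux(ss, -60, 5, sg)
  expect_lt(i, 0)
  expect_gt(f, 0)
  # stoichiometric coupling at steady cycling: charge/glucose = stoich * e
  flux_molec_per_s <- sg$n_transporters *
    (acellsim:::sglt2_transition_rates(-60, 5, sg)$forward[3] * unclass(ss)[3] -
     acellsim:::sglt2_transition_rates(-60, 5, sg)$backward[3] * unclass(ss)[4]) * 1000
  i_amp <- i * 1e-12
  expect_equal(-i_amp / (flux_molec_per_s * 1.602176634e-19),
               sg$na_stoichiometry, tolerance = 1e-8)
  # halving the volume doubles the concentration flux
  expect_equal(sglt2_glucose_flux(ss, -60, 5, sg, cell_volume = 0.4),
               2 * sglt2_glucose_flux(ss, -60, 5, sg, cell_volume = 0.8))
})

test_that("sustained inward current is non-decreasing in glucose up to 20 mM", {
  sg <- acell_default_params()$sglt2
  v <- -50
  mag <- vapply(seq(0, 20, by = 1), function(G)
    -sglt2_current(sglt2_steady_state(v, G, sg), v, G, sg), numeric(1))
  expect_true(all(diff(mag) > -1e-10))
})

test_that("voltage clamp conserves occupancy and decomposes the current", {
  sg <- test_sglt2()
  vc <- sglt2_voltage_clamp(data.frame(duration = c(150, 250, 250),
                                       v = c(-70, -10, -70)),
                            glucose_out = 5, params = sg)
  occ <- as.matrix(vc$trace[, paste0("p", 1:6)])
  expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
  expect_true(all(vc$segments$converged))
  # sustained component is inward under the physiological gradient
  expect_lt(vc$segments$sustained_pa[2], 0)
  # step to the holding potential itself moves no charge
  vc0 <- sglt2_voltage_clamp(data.frame(duration = c(150, 200),
                                        v = c(-70, -70)), 5, sg)
  expect_equal(vc0$segments$transient_pc[2], 0, tolerance = 1e-6)
})

test_that("on and off charge movements balance without glucose", {
  # glucose-free transporter: no cycling, pure reversible charge movement
  sg <- test_sglt2(glucose_in = 0)
  vc <- sglt2_voltage_clamp(data.frame(duration = c(600, 600, 600),
                                       v = c(-70, -10, -70)),
                            glucose_out = 0, params = sg, dt = 0.02)
  q_on <- vc$segments$transient_pc[2]
  q_off <- vc$segments$transient_pc[3]
  expect_gt(abs(q_on), 1e-4)
  expect_equal(q_on, -q_off, tolerance = 0.02)
  # no sustained current without substrate (reversible charge movement only)
  expect_lt(abs(vc$segments$sustained_pa[2]), 1e-3)
})

test_that("constructor derives k16 from detailed balance and validates input", {
  r <- c(k12 = 1e-4, k21 = 0.5, k23 = 0.3, k32 = 2, k34 = 0.01, k43 = 0.01,
         k45 = 0.4, k54 = 0.02, k56 = 0.4, k65 = 1e-3, k61 = 0.05)
  sg <- sglt2_params(rates = r)
  cw <- prod(sg$rates[c("k12", "k23", "k34", "k45", "k56", "k61")])
  ccw <- prod(sg$rates[c("k21", "k32", "k43", "k54", "k65", "k16")])
  expect_equal(cw / ccw, 1, tolerance = 1e-12)
  expect_error(sglt2_params(rates = r[-1]), "missing rate")
  expect_error(sglt2_params(rates = replace(r, 2, -1)), "positive")
})
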