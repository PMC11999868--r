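test_that("L1 scheme reproduces closed-form Caputo derivatives", {
  tau <- 1e-3
  tt <- seq(0, 1, by = tau)
  # derivative of a constant is zero
  expect_equal(caputo_l1(rep(2.5, length(tt)), 0.8, tau),
               rep(0, length(tt)))
  # the L1 scheme is exact for linear signals:
  # D^beta t = t^(1-beta) / gamma(2-beta)
  d_lin <- caputo_l1(tt, 0.8, tau)
  expect_equal(d_lin[-1], tt[-1]^0.2 / gamma(1.2), tolerance = 1e-10)
  # quadratic: D^beta t^2 = 2 t^(2-beta) / gamma(3-beta)
  d_sq <- caputo_l1(tt^2, 0.8, tau)
  expect_equal(d_sq[-1], 2 * tt[-1]^1.2 / gamma(2.2), tolerance = 1e-2)
  expect_error(caputo_l1(tt, 1.2, tau), "strictly in")
})

test_that("L1 error decays at order tau^(2-beta)", {
  beta <- 0.8
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3), function(tau) {
    tt <- seq(0, 1, by = tau)
    max(abs(caputo_l1(tt^2, beta, tau) - 2 * tt^1.2 / gamma(2.2)))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(abs(orders - (2 - beta)) < 0.1))
})

test_that("drag correlation has the Stokes and plateau limits", {
  expect_equal(drag_coefficient(1), 24 + 3 + 0.4)
  expect_equal(drag_coefficient(1e9), 0.4, tolerance = 1e-3)
  # creeping flow: within 1% of Stokes 24/Re
  expect_lt(abs(drag_coefficient(0.01) - 2400) / 2400, 0.01)
  # strictly decreasing
  re <- 10^seq(-3, 6, length.out = 200)
  expect_true(all(diff(drag_coefficient(re)) < 0))
  expect_error(drag_coefficient(0), "positive")
})

test_that("force terms vanish at rest and carry the expected signs", {
  med <- ref_medium(); cell <- cell_layer()
  pu0 <- ultrasound_pulse(p_a = 0, n_cycles = 2)
  tt <- seq(0, 2e-6, by = 5e-9)
  rest <- fake_radial(tt, rep(3e-6, length(tt)), pulse = pu0)
  ft <- force_terms(rest, c(0, 0), 1e-6, pu0, med, cell)
  expect_equal(ft$F_B1 + ft$F_B2 + ft$F_AM + ft$F_VD + ft$F_CR, 0)
  expect_equal(ft$F_I, 0)
  # rebound (Vddot > 0) at 9 um from the wall: mirror force pushes the
  # bubble away from the substrate
  R <- 3e-6 + 0.2e-6 * (tt / 2e-6)^2  # accelerating growth
  reb <- fake_radial(tt, R, pulse = pu0)
  ft2 <- force_terms(reb, c(3e-6, 0), 1e-6, pu0, med, cell)
  expect_gt(approx(reb$t, reb$Vddot, 1e-6)$y, 0)
  expect_lt(ft2$F_B2, 0)
  # cell resistive force opposes compression at a constant strain rate:
  # magnitude pi R^2 c_beta times the Caputo derivative of the ramp
  rate <- 0.05 / 1e-6  # strain per second
  D <- rate * (1e-6)^0.2 / gamma(1.2)  # closed-form Caputo of r*t
  ft3 <- force_terms(rest, c(0.6e-6, rate * cell$L), 1e-6, pu0, med,
                     cell, caputo_eps = D)
  expect_equal(ft3$F_CR, -pi * (3e-6)^2 * cell$c_beta * D)
  expect_lt(ft3$F_CR, 0)
  # geometric violation beyond the substrate
  expect_error(force_terms(rest, c(12.5e-6, 0), 1e-6, pu0, med, cell),
               "substrate")
})

test_that("an undriven bubble does not translate", {
  sol <- solve_radial(ultrasound_pulse(p_a = 0, n_cycles = 5),
                      ref_bubble(), ref_shell(), ref_medium())
  tr <- solve_translation(sol, cell = cell_layer())
  expect_equal(max(abs(tr$x)), 0)
  expect_false(tr$contact$occurred)
})

test_that("the force balance closes on every accepted step", {
  tr <- case_low()$translation
  fr <- tr$forces
  res <- abs(fr$F_I - (fr$F_B1 + fr$F_B2 + fr$F_AM + fr$F_VD + fr$F_CR))
  expect_lt(max(res), 1e-3 * max(abs(fr$F_B1)))
})

test_that("low-amplitude deformation is reversible after the pulse", {
  cs <- case_low()
  tr <- cs$translation
  expect_false(tr$contact$occurred)
  # bubble moves towards the substrate during the pulse...
  expect_gt(max(tr$x), 1e-6)
  # ...and creeps back towards its initial position afterwards
  x_pulse_end <- approx(tr$t, tr$x, cs$pulse$duration)$y
  x_final <- tr$x[length(tr$x)]
  expect_lt(x_final, x_pulse_end)
  expect_lt(x_final, max(tr$x))
})

test_that("the high-amplitude case reaches ultimate compression (tunnel)", {
  tr <- case_high()$translation
  expect_true(tr$contact$occurred)
  expect_gt(max(tr$eps), 0.9)
})

test_that("a stiffer cell is displaced less", {
  sol <- case_low()$radial
  xmax <- vapply(c(0.5, 1, 2), function(cb)
    max(solve_translation(sol, cell = cell_layer(c_beta = cb))$x),
    numeric(1))
  expect_true(all(diff(xmax) < 0))
})

test_that("the trajectory is stable under grid refinement", {
  cs <- case_low()
  sol2 <- solve_radial(cs$pulse, ref_bubble(), ref_shell(),
                       ref_medium(), samples_per_cycle = 400,
                       t_end = 40e-6)
  tr2 <- solve_translation(sol2, cell = cell_layer())
  expect_lt(abs(max(tr2$x) - max(cs$translation$x)) / max(tr2$x),
            5e-3)
})

test_that("beta -> 1 recovers a Newtonian dashpot response", {
  mu_eff <- 0.3
  sol <- case_low()$radial
  tr_frac <- solve_translation(sol, cell = cell_layer(beta = 0.999,
                                                      c_beta = mu_eff))
  # oracle: explicit dashpot F_CR = -pi R^2 mu_eff xdot / L integrated
  # as an ordinary ODE with deSolve
  med <- ref_medium(); pu <- case_low()$pulse; L <- 12e-6
  Rf <- stats::approxfun(sol$t, sol$R, rule = 2)
  Vf <- stats::approxfun(sol$t, sol$V, rule = 2)
  Vdf <- stats::approxfun(sol$t, sol$Vdot, rule = 2)
  Vddf <- stats::approxfun(sol$t, sol$Vddot, rule = 2)
  m0 <- ref_bubble()$rho_g * sol$V[1]
  rhs <- function(t, y, parms) {
    x <- y[1]; v <- y[2]
    R <- Rf(t); V <- Vf(t)
    FB1 <- -V * pulse_gradient(pu, med, t)
    FB2 <- -med$rho_l * V * Vddf(t) / (16 * pi * (L - x)^2)
    Re <- 2 * med$rho_l * R * abs(v) / med$mu_l
    FVD <- -6 * pi * med$mu_l * R * v -
      0.5 * med$rho_l * pi * R^2 * (6 / (1 + sqrt(Re)) + 0.4) * v * abs(v)
    FCR <- -pi * R^2 * mu_eff * v / L
    a <- (FB1 + FB2 + FVD + FCR - 0.5 * med$rho_l * Vdf(t) * v) /
      (m0 + 0.5 * med$rho_l * V)
    list(c(v, a))
  }
  ora <- deSolve::ode(c(x = 0, v = 0), tr_frac$t, rhs, NULL,
                      method = "lsoda", rtol = 1e-8,
                      atol = c(1e-14, 1e-8))
  expect_lt(max(abs(ora[, "x"] - tr_frac$x)) / max(abs(ora[, "x"])),
            0.02)
})

test_that("buoyancy is negligible over the pulse", {
  cs <- case_low()
  buoy <- ref_medium()$rho_l * 9.81 * max(cs$radial$V)
  expect_lt(buoy, 0.01 * max(abs(cs$translation$forces$F_B1)))
})
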