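test_that("jet stresses follow the water-hammer and stagnation formulas", {
  med <- ref_medium()
  js <- jet_stresses(jet_params(u_jet = 60, R_jet = 0.75e-6), med)
  expect_equal(js$p_jet, 0.5 * 998 * 1482 * 60)        # ~44.4 MPa
  expect_equal(js$p_jet / 1e6, 44.4, tolerance = 2e-3)
  expect_equal(js$p_stag, 0.5 * 998 * 60^2)            # ~1.80 MPa
  expect_equal(js$p_stag / 1e6, 1.80, tolerance = 3e-3)
  # hammer duration is the contact radius over the sound speed
  expect_equal(js$varsigma, js$rho_contact / med$c_l)
  # a 30 nm contact radius implies a ~20 ps hammer duration
  js2 <- jet_stresses(jet_params(u_jet = 60,
                                 R_jet = 30e-9 * med$c_l / 60), med)
  expect_equal(js2$rho_contact, 30e-9, tolerance = 1e-10)
  expect_equal(js2$varsigma, 30e-9 / med$c_l, tolerance = 1e-10)
  expect_gt(js2$varsigma, 20e-12)
  # no jet, no stress
  js0 <- jet_stresses(jet_params(u_jet = 0), med)
  expect_equal(unlist(js0), c(p_jet = 0, p_stag = 0, rho_contact = 0,
                              varsigma = 0))
})

test_that("a 6 um bubble crossed within one frame implies >= 60 m/s", {
  expect_equal(min_jet_speed(3e-6, 1e-7), 60)
})

test_that("oscillatory boundary layer and streaming stress match water at 1 MHz", {
  med <- ref_medium()
  sol <- solve_radial(ultrasound_pulse(p_a = 0, n_cycles = 2),
                      ref_bubble(), ref_shell(), med)
  fs <- flow_stresses(sol, u_stream = 0.1)
  expect_equal(fs$delta, sqrt(2 * 1e-3 / (998 * 2 * pi * 1e6)))
  expect_equal(fs$delta * 1e6, 0.565, tolerance = 1e-3)
  # tau_stream ~ 177 Pa: "below a few hundreds of pascals"
  expect_equal(fs$tau_stream, 1e-3 * 0.1 / fs$delta)
  expect_lt(fs$tau_stream, 300)
  expect_equal(fs$tau_stream / 1e2, 1.8, tolerance = 0.02)
  # a static interface exerts no impact or shear stress
  expect_equal(max(abs(fs$p_impact)), 0, tolerance = 1e-10)
  expect_equal(max(abs(fs$tau_shear)), 0, tolerance = 1e-10)
})

test_that("Bjerknes cross-section pressures carry sign and scaling", {
  med <- ref_medium()
  pu0 <- ultrasound_pulse(p_a = 0, n_cycles = 2)
  tt <- seq(0, 2e-6, by = 1e-9)
  # accelerating growth: Vddot > 0 so the mirror pulls away (p_B2 < 0)
  R <- 3e-6 + 0.2e-6 * (tt / 2e-6)^2
  sol <- fake_radial(tt, R, pulse = pu0)
  bp <- bjerknes_pressures(sol, h = 9e-6, sample_rate = NULL)
  mid <- floor(length(bp$t) / 2)
  expect_lt(bp$p_B2[mid], 0)
  # no driving gradient, no primary Bjerknes pressure
  expect_equal(max(abs(bp$p_B1)), 0, tolerance = 1e-20)
  # doubling the distance quarters the mirror pressure
  bp2 <- bjerknes_pressures(sol, h = 18e-6, sample_rate = NULL)
  expect_equal(bp$p_B2[mid] / bp2$p_B2[mid], 4, tolerance = 1e-10)
  expect_error(bjerknes_pressures(sol, h = -1e-6), "positive")
})

test_that("stress channels scale with density as the formulas demand", {
  pu <- ultrasound_pulse(p_a = 60e3, n_cycles = 6)
  sol <- solve_radial(pu, ref_bubble(), ref_shell(), ref_medium())
  m1 <- ref_medium()
  m2 <- medium(rho_l = 2 * 998)
  jet <- jet_params()
  j1 <- jet_stresses(jet, m1); j2 <- jet_stresses(jet, m2)
  expect_equal(j2$p_jet / j1$p_jet, 2)
  expect_equal(j2$p_stag / j1$p_stag, 2)
  f1 <- flow_stresses(sol, med = m1)
  f2 <- flow_stresses(sol, med = m2)
  # same kinematics: impact pressure linear in rho, shear stress
  # sqrt(rho) through the boundary layer
  expect_equal(max(abs(f2$p_impact)) / max(abs(f1$p_impact)), 2,
               tolerance = 1e-10)
  expect_equal(f2$tau_stream / f1$tau_stream, sqrt(2),
               tolerance = 1e-10)
  expect_equal(max(abs(f2$tau_shear)) / max(abs(f1$tau_shear)),
               sqrt(2), tolerance = 1e-10)
})

test_that("the assembled report is structurally consistent", {
  cs <- case_high()
  rep <- stress_report(cs$radial, cs$translation)
  expect_setequal(rep$peaks$mechanism,
                  c("p_jet", "p_stag", "p_impact", "tau_shear",
                    "tau_stream", "p_B1", "p_B2"))
  # water-hammer exceeds stagnation which exceeds the wall impact
  # pressure whenever the wall is slower than the jet
  pk <- function(m) rep$peaks$peak[rep$peaks$mechanism == m]
  expect_gt(pk("p_jet"), pk("p_stag"))
  expect_gt(pk("p_stag"), pk("p_impact"))
  # jets fire at compression peaks only after the expansion threshold
  expect_true(length(rep$jet_times) > 0)
  expect_gt(min(rep$jet_times), 2e-6)  # not during the early ramp
  # zero driving: everything quiet except streaming
  sol0 <- solve_radial(ultrasound_pulse(p_a = 0, n_cycles = 2),
                       ref_bubble(), ref_shell(), ref_medium())
  rep0 <- stress_report(sol0, u_stream = 0.1)
  expect_equal(max(abs(rep0$series$p_impact)), 0, tolerance = 1e-10)
  expect_equal(max(abs(rep0$series$p_jet)), 0)
  expect_gt(rep0$series$tau_stream[1], 0)
})
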