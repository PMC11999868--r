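test_that("Marmottant surface tension has the three regimes and is clamped", {
  sh <- shell_params(chi = 0.5, kappa_s = 7e-9, sigma_R0 = 0.02)
  # choose R0 so that the buckling radius is exactly 2.9 um
  R0 <- 2.9e-6 * sqrt(1 + sh$sigma_R0 / sh$chi)
  rr <- marmottant_radii(sh, R0)
  expect_equal(rr[["R_b"]], 2.9e-6)
  expect_equal(surface_tension(rr[["R_b"]], sh, R0), 0)
  expect_equal(surface_tension(rr[["R_r"]], sh, R0), 0.072)
  # elastic branch: chi ((R/R_b)^2 - 1)
  expect_equal(surface_tension(2.95e-6, sh, R0),
               0.5 * ((2.95 / 2.9)^2 - 1), tolerance = 1e-10)
  expect_equal(surface_tension(2.95e-6, sh, R0), 0.0174,
               tolerance = 2e-3)
  # nondecreasing and clamped to [0, sigma_w]
  sig <- surface_tension(seq(0.5 * R0, 2 * R0, length.out = 500), sh, R0)
  expect_true(all(diff(sig) >= 0))
  expect_true(all(sig >= 0 & sig <= 0.072))
  # initial tension is recovered at R0
  expect_equal(surface_tension(R0, sh, R0), sh$sigma_R0,
               tolerance = 1e-10)
})

test_that("an undriven bubble stays at its equilibrium radius", {
  sol <- solve_radial(ultrasound_pulse(p_a = 0), ref_bubble(),
                      ref_shell(), ref_medium(), t_end = 20e-6)
  expect_lt(max(abs(sol$R - 3e-6)) / 3e-6, 1e-6)
  expect_equal(sol$V, 4 / 3 * pi * sol$R^3)
})

test_that("small-amplitude response matches the linearized oscillator", {
  pu <- ultrasound_pulse(p_a = 1e3)
  sol <- solve_radial(pu, ref_bubble(), ref_shell(), ref_medium())
  lin <- linear_radial_response(pu, ref_bubble(), ref_shell(),
                                ref_medium())
  late <- sol$t > 10e-6 & sol$t < 20e-6  # steady state, past the ramp
  amp <- (max(sol$R[late]) - min(sol$R[late])) / 2
  expect_lt(abs(amp - lin$amplitude) / lin$amplitude, 0.05)
})

test_that("the high-amplitude reference case expands past the jetting threshold", {
  cs <- case_high()
  em <- expansion_metrics(cs$radial)
  expect_gt(em$max_expansion, 1e-6)
  expect_true(classify_event(em$max_expansion, 3e-6)$jetting)
})

test_that("oscillation energy decays after the pulse ends", {
  cs <- case_low()
  pu <- cs$pulse
  sol <- cs$radial
  # per-cycle envelope of |R - R0| over the ring-down
  post_cycles <- seq(ceiling(pu$duration * pu$f) + 1, 38)
  env <- vapply(post_cycles, function(n) {
    idx <- sol$t >= (n - 1) / pu$f & sol$t <= n / pu$f
    max(abs(sol$R[idx] - 3e-6))
  }, numeric(1))
  expect_true(all(diff(env) <= 1e-12))
})

test_that("expansion metrics reproduce the acceleration proxy arithmetic", {
  # synthetic solution with exactly 1 um maximum expansion at 1 MHz
  pu <- ultrasound_pulse(p_a = 1e5, n_cycles = 4)
  tt <- seq(0, 4e-6, by = 5e-9)
  amps <- c(0.25, 0.5, 1, 0.75) # per-cycle expansion amplitudes (um)
  R <- 3e-6 + 1e-6 * amps[pmin(floor(tt * 1e6) + 1, 4)] *
    sin(2 * pi * 1e6 * tt)^2
  sol <- fake_radial(tt, R, pulse = pu)
  em <- expansion_metrics(sol)
  om2 <- (2 * pi * 1e6)^2
  expect_equal(em$max_expansion, 1e-6, tolerance = 1e-6)
  expect_equal(em$accel_proxy, 1e-6 * om2, tolerance = 1e-6)
  # in um/us^2 this is ~39.5, the jetting threshold scale
  expect_equal(em$accel_proxy / 1e6, 39.478, tolerance = 1e-3)
  expect_equal(em$per_cycle$max_expansion, 1e-6 * amps,
               tolerance = 1e-3)
  expect_equal(em$per_cycle$accel_proxy[2], 0.5e-6 * om2,
               tolerance = 1e-3)
  # no expansion, no proxy
  em0 <- expansion_metrics(fake_radial(tt, rep(3e-6, length(tt)),
                                       pulse = pu))
  expect_equal(em0$max_expansion, 0)
  expect_equal(em0$accel_proxy, 0)
})

test_that("event classification applies both threshold rules", {
  # stable-cavitation jetting: above 1 um expansion, below 2 R0
  cls <- classify_event(1.2e-6, 3e-6)
  expect_true(cls$jetting && cls$sonoporation_predicted)
  expect_false(cls$inertial_cavitation)
  # boundary: just below the default threshold
  expect_false(classify_event(0.99e-6, 3e-6)$jetting)
  # small bubble: both jetting and inertial cavitation
  cls2 <- classify_event(1.0e-6, 0.8e-6)
  expect_true(cls2$jetting && cls2$inertial_cavitation)
  expect_error(classify_event(1e-6, 3e-6, jet_threshold = 0),
               "positive")
})

test_that("halving the solver tolerance leaves the expansion unchanged", {
  cs <- case_low()
  ref <- max(cs$radial$R) - 3e-6
  sol2 <- solve_radial(cs$pulse, ref_bubble(), ref_shell(),
                       ref_medium(), t_end = 40e-6, rtol = 5e-9)
  expect_lt(abs((max(sol2$R) - 3e-6) - ref) / ref, 1e-3)
})

test_that("amplitude fitting is self-consistent and monotone", {
  med <- ref_medium(); sh <- ref_shell(); bub <- ref_bubble()
  tmpl <- ultrasound_pulse(p_a = 100e3, n_cycles = 8)
  # noiseless track generated at factor 1 is recovered exactly
  tr0 <- gen_radius_track(tmpl, bub, sh, med, synthetic_spec(seed = 1),
                          noise = 0)
  fit0 <- fit_amplitude(tr0$track, tmpl, bub, sh, med)
  expect_lt(abs(fit0$factor - 1), 1e-3)
  # larger true amplitude gives a larger fitted factor
  hi <- tmpl; hi$p_a <- 160e3
  lo <- tmpl; lo$p_a <- 120e3
  tr_hi <- gen_radius_track(hi, bub, sh, med, synthetic_spec(seed = 2))
  tr_lo <- gen_radius_track(lo, bub, sh, med, synthetic_spec(seed = 2))
  f_hi <- fit_amplitude(tr_hi$track, tmpl, bub, sh, med)$factor
  f_lo <- fit_amplitude(tr_lo$track, tmpl, bub, sh, med)$factor
  expect_gt(f_hi, f_lo)
  expect_equal(f_hi, 1.6, tolerance = 0.02)
  # a track outside the pulse window is rejected
  off <- tr0$track
  off$t_s <- off$t_s + 1
  expect_error(fit_amplitude(off, tmpl, bub, sh, med), "overlap")
  # a flat track is flagged ill-posed
  flat <- data.frame(t_s = tr0$track$t_s, R_m = rep(3e-6, nrow(tr0$track)))
  expect_warning(fit_amplitude(flat, tmpl, bub, sh, med), "ill-posed")
})
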