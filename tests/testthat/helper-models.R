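# Shared model objects and lazily cached reference solutions. The two
# case-study simulations (60 and 160 kPa, R0 = 3 um, 1 MHz, 20-cycle
# ramp) are expensive enough to share across test files.

ref_medium <- function() medium()
ref_shell <- function() shell_params()
ref_bubble <- function() bubble_params()

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, make(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

case_high <- function() fixture("case_high", function() {
  pu <- ultrasound_pulse(p_a = 160e3)
  sol <- solve_radial(pu, ref_bubble(), ref_shell(), ref_medium())
  tr <- solve_translation(sol, cell = cell_layer())
  list(pulse = pu, radial = sol, translation = tr)
})

# low-amplitude case run past the pulse so post-pulse relaxation is
# visible
case_low <- function() fixture("case_low", function() {
  pu <- ultrasound_pulse(p_a = 60e3)
  sol <- solve_radial(pu, ref_bubble(), ref_shell(), ref_medium(),
                      t_end = 40e-6)
  tr <- solve_translation(sol, cell = cell_layer())
  list(pulse = pu, radial = sol, translation = tr)
})

# growth + collapse of an inviscid vapour bubble under constant driving
# pressure: the analytic reference case of the Kelvin-impulse framework
vapour_growth_collapse <- function(R0 = 1e-3, dp = 1e5, rho = 998) {
  rc <- sonojet:::rayleigh_collapse(R0 = R0, dp = dp, rho = rho)
  t_growth <- max(rc$t) - rev(rc$t)
  list(t = c(t_growth, rc$t + max(rc$t)),
       R = c(rev(rc$R), rc$R),
       R0 = R0, dp = dp, rho = rho)
}

# minimal radial_solution stand-in for tests that only need R(t)
fake_radial <- function(t, R, bubble = ref_bubble(),
                        pulse = ultrasound_pulse(p_a = 0),
                        med = ref_medium()) {
  dt <- t[2] - t[1]
  Rd <- c(0, diff(R)) / dt
  V <- 4 / 3 * pi * R^3
  structure(list(t = t, R = R, Rdot = Rd, Rddot = rep(0, length(t)),
                 V = V, Vdot = c(0, diff(V)) / dt,
                 Vddot = c(0, diff(V, differences = 2) / dt^2, 0),
                 tau = dt, pulse = pulse, bubble = bubble,
                 med = med),
            class = "radial_solution")
}
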