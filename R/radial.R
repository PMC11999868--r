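#' Lipid-shell (Marmottant) parameters
#'
#' Parameters of the piecewise surface-tension law for a phospholipid
#' coated bubble: buckled (`sigma = 0`), elastic
#' (`sigma = chi (R^2/R_b^2 - 1)`) and ruptured (`sigma = sigma_w`)
#' regimes, plus a surface dilatational viscosity. The buckling and
#' rupture radii follow from the initial tension:
#' `R_b = R0 / sqrt(1 + sigma_R0/chi)`,
#' `R_r = R_b sqrt(1 + sigma_w/chi)`.
#'
#' Defaults are typical literature values for DSPC-based lipid shells;
#' they are not printed measurements and every downstream threshold or
#' ratio should be read with that in mind.
#'
#' @param chi Shell elastic modulus (N m^-1), positive.
#' @param kappa_s Shell surface dilatational viscosity (kg s^-1).
#' @param sigma_R0 Initial surface tension at the equilibrium radius
#'   (N m^-1), in `[0, sigma_w]`.
#'
#' @return An object of class `shell_params`.
#' @export
shell_params <- function(chi = 0.5, kappa_s = 7e-9, sigma_R0 = 0.02) {
  if (!is.finite(chi) || chi <= 0) stop("chi must be positive")
  if (!is.finite(kappa_s) || kappa_s < 0) stop("kappa_s must be non-negative")
  if (!is.finite(sigma_R0) || sigma_R0 < 0)
    stop("sigma_R0 must be non-negative")
  structure(list(chi = chi, kappa_s = kappa_s, sigma_R0 = sigma_R0),
            class = "shell_params")
}

#' Bubble parameters
#'
#' Equilibrium radius and reduced gas model of the bubble core. The gas
#' follows `p_g = p_g0 (R0/R)^(3 kappa)` with the polytropic exponent
#' selected by `gas_model`: `"polytropic"` uses `kappa` as given
#' (default 1.07, appropriate for a perfluorobutane-like core),
#' `"isothermal"` forces `kappa = 1` and `"adiabatic"` uses the heat
#' capacity ratio `gamma`. The initial gas pressure follows from
#' mechanical equilibrium: `p_g0 = p0 - p_v + 2 sigma(R0)/R0`.
#'
#' @param R0 Equilibrium radius (m), positive.
#' @param gas_model One of `"polytropic"`, `"isothermal"`, `"adiabatic"`.
#' @param kappa Polytropic exponent used by `gas_model = "polytropic"`.
#' @param gamma Heat capacity ratio used by `gas_model = "adiabatic"`.
#' @param rho_g Gas density at equilibrium (kg m^-3); sets the (small
#'   but retained) bubble mass in the translational force balance.
#'
#' @return An object of class `bubble_params`.
#' @export
bubble_params <- function(R0 = 3e-6,
                          gas_model = c("polytropic", "isothermal",
                                        "adiabatic"),
                          kappa = 1.07, gamma = 1.07, rho_g = 10) {
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be positive")
  gas_model <- match.arg(gas_model)
  kap <- switch(gas_model, polytropic = kappa, isothermal = 1,
                adiabatic = gamma)
  if (kap < 1) stop("polytropic exponent must be >= 1")
  structure(list(R0 = R0, gas_model = gas_model, kappa = kap,
                 gamma = gamma, rho_g = rho_g),
            class = "bubble_params")
}

#' Buckling and rupture radii of a coated bubble
#'
#' @param shell A [shell_params()].
#' @param R0 Equilibrium radius (m).
#' @param sigma_w Clean-interface surface tension (N m^-1).
#' @return Named numeric vector with `R_b` and `R_r` (m).
#' @export
marmottant_radii <- function(shell, R0, sigma_w = 0.072) {
  R_b <- R0 / sqrt(1 + shell$sigma_R0 / shell$chi)
  R_r <- R_b * sqrt(1 + sigma_w / shell$chi)
  c(R_b = R_b, R_r = R_r)
}

#' Effective surface tension of the lipid shell
#'
#' Marmottant piecewise law: 0 below the buckling radius,
#' `chi (R^2/R_b^2 - 1)` in the elastic regime, `sigma_w` beyond the
#' rupture radius. Piecewise continuous, nondecreasing in `R` and
#' clamped to `[0, sigma_w]`.
#'
#' @param R Radius (m), vectorized.
#' @param shell A [shell_params()].
#' @param R0 Equilibrium radius (m) fixing the buckling radius.
#' @param sigma_w Clean-interface surface tension (N m^-1).
#' @return Effective surface tension (N m^-1).
#' @examples
#' sh <- shell_params(chi = 0.5, sigma_R0 = 0.02)
#' surface_tension(3e-6, sh, R0 = 3e-6) # = sigma_R0
#' @export
surface_tension <- function(R, shell, R0, sigma_w = 0.072) {
  rr <- marmottant_radii(shell, R0, sigma_w)
  s <- shell$chi * ((R / rr[["R_b"]])^2 - 1)
  pmin(pmax(s, 0), sigma_w)
}

## scalar sigma and its radius-derivative for the solver hot path
sigma_and_slope <- function(R, chi, R_b, R_r, sigma_w) {
  if (R <= R_b) return(c(0, 0))
  if (R >= R_r) return(c(sigma_w, 0))
  c(chi * ((R / R_b)^2 - 1), 2 * chi * R / R_b^2)
}

## Keller-Miksis RHS with Marmottant shell; returns d(R, Rdot)/dt.
## Collects the Rddot contributions of the R/(rho c) dp_L/dt viscous
## terms on the left-hand side before inversion.
radial_derivs <- function(t, R, Rd, pr) {
  sg <- sigma_and_slope(R, pr$chi, pr$R_b, pr$R_r, pr$sigma_w)
  sig <- sg[1]; dsig <- sg[2]
  pg <- pr$p_g0 * (pr$R0 / R)^(3 * pr$kappa)
  p_d <- pr$pd(t)
  pL <- pg + pr$p_v - 2 * sig / R - 4 * pr$mu_l * Rd / R -
    4 * pr$kappa_s * Rd / R^2
  dpg <- -3 * pr$kappa * pg * Rd / R
  ## d/dt of pL excluding the Rddot terms of the viscous contributions
  dpL_noacc <- dpg - 2 * Rd * (dsig / R - sig / R^2) +
    4 * pr$mu_l * Rd^2 / R^2 + 8 * pr$kappa_s * Rd^2 / R^3
  cc <- pr$c_l; rho <- pr$rho_l
  lhs <- (1 - Rd / cc) * R + (4 * pr$mu_l / R + 4 * pr$kappa_s / R^2) *
    R / (rho * cc)
  rhs <- -1.5 * (1 - Rd / (3 * cc)) * Rd^2 +
    (1 + Rd / cc) * (pL - pr$p0 - p_d) / rho +
    R / (rho * cc) * (dpL_noacc - pr$pd_dot(t))
  c(Rd, rhs / lhs)
}

## incompressible modified Rayleigh-Plesset variant (radiation damping
## only through the gas-pressure convection term), kept for comparison
radial_derivs_rp <- function(t, R, Rd, pr) {
  sg <- sigma_and_slope(R, pr$chi, pr$R_b, pr$R_r, pr$sigma_w)
  sig <- sg[1]
  pg <- pr$p_g0 * (pr$R0 / R)^(3 * pr$kappa)
  num <- pg * (1 - 3 * pr$kappa * Rd / pr$c_l) - pr$p0 + pr$p_v -
    2 * sig / R - 4 * pr$mu_l * Rd / R - 4 * pr$kappa_s * Rd / R^2 -
    pr$pd(t) - 1.5 * pr$rho_l * Rd^2
  c(Rd, num / (pr$rho_l * R))
}

#' Solve the coated-bubble radial dynamics
#'
#' Integrates the spherically symmetric radial motion of a lipid-coated
#' bubble driven by an ultrasound pulse: Keller-Miksis first-order
#' compressible liquid (or, optionally, an incompressible modified
#' Rayleigh-Plesset form), Marmottant shell tension and viscosity, and
#' the reduced gas law configured in [bubble_params()]. The solution is
#' returned on a uniform grid (at least 50 samples per carrier period)
#' together with volume derivatives, as needed by the translational and
#' impulse analyses.
#'
#' @param pulse An [ultrasound_pulse()].
#' @param bubble A [bubble_params()].
#' @param shell A [shell_params()].
#' @param med A [medium()].
#' @param samples_per_cycle Output samples per carrier period (>= 50).
#' @param t_end End of the integration window (s); default 1.1 times the
#'   pulse duration so ring-down is visible.
#' @param rtol,atol_R Relative tolerance and radius absolute tolerance of
#'   the stiff adaptive integrator.
#' @param compressibility `"keller-miksis"` (default) or `"none"`.
#'
#' @return An object of class `radial_solution`: a list with the uniform
#'   time grid `t`, radius `R` and derivatives `Rdot`, `Rddot`, volume
#'   `V` and derivatives `Vdot`, `Vddot`, plus the input objects and grid
#'   step `tau`.
#' @examples
#' sol <- solve_radial(ultrasound_pulse(p_a = 0, n_cycles = 2),
#'                     bubble_params(), shell_params(), medium())
#' max(abs(sol$R - 3e-6)) # stays at equilibrium
#' @export
solve_radial <- function(pulse, bubble, shell, med,
                         samples_per_cycle = 200, t_end = NULL,
                         rtol = 1e-8, atol_R = NULL,
                         compressibility = c("keller-miksis", "none")) {
  compressibility <- match.arg(compressibility)
  if (samples_per_cycle < 50)
    stop("samples_per_cycle must be at least 50")
  R0 <- bubble$R0
  rr <- marmottant_radii(shell, R0, med$sigma_w)
  p_g0 <- med$p0 - med$p_v + 2 * shell$sigma_R0 / R0
  pr <- list(R0 = R0, kappa = bubble$kappa, p_g0 = p_g0,
             chi = shell$chi, kappa_s = shell$kappa_s,
             R_b = rr[["R_b"]], R_r = rr[["R_r"]],
             rho_l = med$rho_l, mu_l = med$mu_l, c_l = med$c_l,
             p0 = med$p0, p_v = med$p_v, sigma_w = med$sigma_w,
             pd = scalar_pd(pulse), pd_dot = scalar_pd_dot(pulse))
  deriv <- if (compressibility == "keller-miksis") radial_derivs
           else radial_derivs_rp
  if (is.null(t_end)) t_end <- pulse$duration * 1.1
  tau <- 1 / (samples_per_cycle * pulse$f)
  times <- seq(0, t_end, by = tau)
  if (is.null(atol_R)) atol_R <- R0 * 1e-10
  rhs <- function(t, y, parms) list(deriv(t, y[1], y[2], pr))
  sol <- ode(c(R = R0, Rdot = 0), times, rhs, NULL, method = "lsoda",
             rtol = rtol, atol = c(atol_R, 1e-6))
  if (nrow(sol) < length(times) || any(!is.finite(sol[, "R"])) ||
      min(sol[, "R"]) < R0 * 1e-3) {
    ok <- is.finite(sol[, "R"]) & sol[, "R"] >= R0 * 1e-3
    last <- max(which(ok))
    stop(sprintf(paste0("radial integration failed (collapse beyond ",
                        "resolution) at t = %.4g s; last valid R = %.4g m"),
                 sol[last, "time"], sol[last, "R"]))
  }
  R <- sol[, "R"]; Rd <- sol[, "Rdot"]
  Rdd <- vapply(seq_along(times),
                function(i) deriv(times[i], R[i], Rd[i], pr)[2], numeric(1))
  V <- 4 / 3 * pi * R^3
  Vd <- 4 * pi * R^2 * Rd
  Vdd <- 4 * pi * (2 * R * Rd^2 + R^2 * Rdd)
  structure(list(t = times, R = R, Rdot = Rd, Rddot = Rdd,
                 V = V, Vdot = Vd, Vddot = Vdd, tau = tau,
                 pulse = pulse, bubble = bubble, shell = shell,
                 med = med, compressibility = compressibility),
            class = "radial_solution")
}

#' @export
print.radial_solution <- function(x, ...) {
  cat(sprintf(
    "radial solution: R0 = %g um, %d samples, dt = %.3g ns\n",
    x$bubble$R0 * 1e6, length(x$t), x$tau * 1e9))
  cat(sprintf("  R in [%.3g, %.3g] um, max |Rdot| = %.3g m/s\n",
              min(x$R) * 1e6, max(x$R) * 1e6, max(abs(x$Rdot))))
  invisible(x)
}

#' Linearized small-amplitude response of a coated bubble
#'
#' Closed-form eigenfrequency and steady-state radial oscillation
#' amplitude of the Marmottant-coated bubble in the elastic shell
#' regime, used as an independent check of the nonlinear solver in the
#' small-amplitude limit.
#'
#' @inheritParams solve_radial
#' @return List with `f0` (undamped eigenfrequency, Hz), `amplitude`
#'   (steady-state amplitude of `R - R0`, m) and `damping_b` (total
#'   damping coefficient, Pa s).
#' @export
linear_radial_response <- function(pulse, bubble, shell, med) {
  R0 <- bubble$R0
  p_g0 <- med$p0 - med$p_v + 2 * shell$sigma_R0 / R0
  rr <- marmottant_radii(shell, R0, med$sigma_w)
  dsig <- 2 * shell$chi * R0 / rr[["R_b"]]^2
  K <- 3 * bubble$kappa * p_g0 + 2 * dsig - 2 * shell$sigma_R0 / R0
  om0 <- sqrt(K / (med$rho_l * R0^2))
  b <- 4 * med$mu_l + 4 * shell$kappa_s / R0 +
    3 * bubble$kappa * p_g0 * R0 / med$c_l
  om <- 2 * pi * pulse$f
  xamp <- (pulse$p_a / (med$rho_l * R0^2)) /
    sqrt((om0^2 - om^2)^2 + (b * om / (med$rho_l * R0^2))^2)
  list(f0 = om0 / (2 * pi), amplitude = xamp * R0, damping_b = b)
}

#' Fit the pressure-amplification factor from a radius track
#'
#' The in-chamber pressure amplitude differs from the hydrophone
#' free-field value because of absorption by neighbouring bubbles and
#' reflections. Following standard practice, the amplitude is inferred
#' as the only fitting parameter from a measured radius-time curve: a
#' bounded 1-D least-squares search over the multiplicative factor
#' applied to the template pulse amplitude.
#'
#' @param observed Data frame with columns `t_s` (s) and `R_m` (m): the
#'   measured radius track (typical uncertainty: half a pixel, 80 nm).
#' @param pulse Template pulse; `pulse$p_a` is the nominal (hydrophone)
#'   amplitude the factor multiplies.
#' @param bubble,shell,med Remaining model parameters, held fixed.
#' @param factor_range Bounds of the 1-D search (unitless).
#' @param tol Convergence tolerance on the factor.
#' @param ... Passed to [solve_radial()].
#'
#' @return List with `factor` (unitless), `p_a_fit` (Pa), `residual_rms`
#'   (m) and `n_obs`.
#' @export
fit_amplitude <- function(observed, pulse, bubble, shell, med,
                          factor_range = c(0.2, 5), tol = 1e-4, ...) {
  if (!all(c("t_s", "R_m") %in% names(observed)))
    stop("observed track needs columns 't_s' and 'R_m'")
  keep <- observed$t_s >= 0 & observed$t_s <= pulse$duration * 1.1
  obs <- observed[keep, ]
  if (nrow(obs) < 5)
    stop("observed track does not overlap the pulse window")
  if (diff(range(obs$R_m)) < 1e-12 * bubble$R0)
    warning("observed radius track is flat; amplitude fit is ill-posed")
  ssr <- function(fac) {
    pu <- pulse
    pu$p_a <- pulse$p_a * fac
    sol <- solve_radial(pu, bubble, shell, med, ...)
    Rhat <- approx(sol$t, sol$R, xout = obs$t_s, rule = 2)$y
    sum((Rhat - obs$R_m)^2)
  }
  opt <- optimize(ssr, interval = factor_range, tol = tol)
  list(factor = opt$minimum, p_a_fit = pulse$p_a * opt$minimum,
       residual_rms = sqrt(opt$objective / nrow(obs)), n_obs = nrow(obs))
}

#' Expansion and acceleration metrics of a radial solution
#'
#' Computes the maximum radial expansion `max(R) - R0`, the interfacial
#' acceleration proxy `(R_max - R0) omega^2` used to interpret the
#' jetting threshold, and the same two quantities per carrier cycle (for
#' first-jet timing analyses).
#'
#' @param sol A [solve_radial()] result.
#' @param bubble,pulse Defaults taken from `sol`.
#' @return List with `max_expansion` (m), `accel_proxy` (m s^-2) and
#'   `per_cycle`, a data frame with one row per full carrier cycle
#'   (`cycle`, `max_expansion`, `accel_proxy`).
#' @examples
#' # 1 um expansion at 1 MHz corresponds to ~39.5 um/us^2
#' 1e-6 * (2 * pi * 1e6)^2 / 1e6
#' @export
expansion_metrics <- function(sol, bubble = sol$bubble,
                              pulse = sol$pulse) {
  om2 <- (2 * pi * pulse$f)^2
  mx <- max(sol$R) - bubble$R0
  per <- lapply(seq_len(pulse$n_cycles), function(n) {
    idx <- sol$t >= (n - 1) / pulse$f & sol$t <= n / pulse$f
    if (!any(idx)) return(NULL)
    me <- max(sol$R[idx]) - bubble$R0
    data.frame(cycle = n, max_expansion = me, accel_proxy = me * om2)
  })
  list(max_expansion = mx, accel_proxy = mx * om2,
       per_cycle = do.call(rbind, per))
}

#' Classify a bubble event against jetting and cavitation thresholds
#'
#' Jetting (and hence predicted sonoporation) when the maximum radial
#' expansion reaches the critical threshold (default 1 um, independent
#' of equilibrium radius); inertial cavitation when the bubble expands
#' to at least twice its equilibrium radius.
#'
#' @param max_expansion Maximum radial expansion `max(R) - R0` (m).
#' @param R0 Equilibrium radius (m).
#' @param jet_threshold Expansion threshold for jetting (m).
#' @param ic_factor Inertial-cavitation radius multiple of `R0`.
#' @return List of logicals: `jetting`, `sonoporation_predicted`,
#'   `inertial_cavitation`.
#' @examples
#' classify_event(1.2e-6, 3e-6) # stable-cavitation jetting
#' @export
classify_event <- function(max_expansion, R0, jet_threshold = 1e-6,
                           ic_factor = 2) {
  if (jet_threshold <= 0 || ic_factor <= 0)
    stop("thresholds must be positive")
  jet <- max_expansion >= jet_threshold
  list(jetting = jet,
       sonoporation_predicted = jet,
       inertial_cavitation = (R0 + max_expansion) >= ic_factor * R0)
}
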