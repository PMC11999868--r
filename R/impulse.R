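## Kelvin-impulse prefactor of the constant-pressure vapour-bubble
## growth-collapse (|I| = C R0^4 |grad p| sqrt(rho/dp), C ~ 4.789)
RAYLEIGH_PREFACTOR_ANALYTIC <- function() {
  2 * (4 / 3) * pi * sqrt(3 / 2) * (1 / 3) * beta(11 / 6, 1 / 2)
}

#' Kelvin impulse from volume and pressure-gradient series
#'
#' The Kelvin impulse measures the linear momentum acquired by the fluid
#' over a bubble's expansion-compression period:
#' `I = -integral of V(t) grad p(t) dt` over the window (trapezoidal
#' quadrature).
#'
#' @param t Time grid (s).
#' @param V Bubble volume series (m^3) on `t`.
#' @param grad_p Pressure-gradient series (Pa m^-1, signed along the
#'   substrate normal) on `t`.
#' @param window Length-2 numeric `(t_start, t_end)`; must lie inside
#'   the data range.
#' @return Impulse (kg m s^-1), signed along the substrate normal.
#' @export
kelvin_impulse <- function(t, V, grad_p, window = range(t)) {
  if (window[1] < min(t) - 1e-12 * diff(range(t)) ||
      window[2] > max(t) + 1e-12 * diff(range(t)))
    stop("impulse window lies outside the data range")
  idx <- t >= window[1] & t <= window[2]
  if (sum(idx) < 3) stop("impulse window contains too few samples")
  -trapz(t[idx], V[idx] * grad_p[idx])
}

## Rayleigh growth-collapse of an inviscid, zero-surface-tension vapour
## bubble under constant driving pressure dp: returns time series and
## the time integral of V over growth + collapse. Collapse is integrated
## from R0 at rest down to r_stop*R0; growth is its time mirror.
rayleigh_collapse <- function(R0 = 1, dp = 1, rho = 1, r_stop = 1e-3,
                              n_out = 4000) {
  rhs <- function(t, y, parms) {
    R <- y[1]; Rd <- y[2]
    list(c(Rd, (-dp / rho - 1.5 * Rd^2) / R),
         NULL)
  }
  root <- function(t, y, parms) y[1] - r_stop * R0
  ## Rayleigh collapse time ~ 0.9147 R0 sqrt(rho/dp)
  t_guess <- 0.9147 * R0 * sqrt(rho / dp)
  times <- seq(0, 1.05 * t_guess, length.out = n_out)
  sol <- ode(c(R = R0, Rd = 0), times, rhs, NULL, method = "lsodar",
             rtol = 1e-10, atol = c(R0 * 1e-12, 1e-8),
             rootfunc = root)
  keep <- is.finite(sol[, "R"]) & sol[, "R"] > 0
  list(t = sol[keep, "time"], R = sol[keep, "R"], Rd = sol[keep, "Rd"])
}

#' Kelvin-impulse prefactor for constant driving pressure
#'
#' Numerically evaluates the unitless prefactor in the closed-form
#' Kelvin impulse of an inviscid, zero-surface-tension vapour bubble
#' undergoing growth and collapse under a constant driving pressure
#' `dp` and unit pressure gradient:
#' `|I| / (R0^4 |grad p| sqrt(rho/dp))`. The `"ode"` method integrates
#' the collapse in time and doubles the (symmetric) growth phase; the
#' `"quadrature"` method evaluates the equivalent radius-domain integral
#' `2 (4/3) pi sqrt(3/2) int_0^1 u^(9/2) (1-u^3)^(-1/2) du`. The
#' analytic value is `2 (4/3) pi sqrt(3/2) (1/3) B(11/6, 1/2)` = 4.7888.
#'
#' @param method `"ode"` (default) or `"quadrature"`.
#' @param phase `"growth+collapse"` (default) or `"collapse"` for the
#'   collapse-only half.
#' @return The unitless prefactor (~4.789, or ~2.394 for collapse only).
#' @examples
#' rayleigh_prefactor(method = "quadrature")
#' @export
rayleigh_prefactor <- function(method = c("ode", "quadrature"),
                               phase = c("growth+collapse", "collapse")) {
  method <- match.arg(method)
  phase <- match.arg(phase)
  half <- if (phase == "collapse") 1 else 2
  if (method == "quadrature") {
    J <- stats::integrate(function(u) u^4.5 / sqrt(1 - u^3), 0, 1,
                          rel.tol = 1e-10)$value
    return(half * (4 / 3) * pi * sqrt(3 / 2) * J)
  }
  rc <- rayleigh_collapse(R0 = 1, dp = 1, rho = 1)
  J <- trapz(rc$t, 4 / 3 * pi * rc$R^3)
  half * J  # R0 = dp = rho = |grad p| = 1
}

#' Equivalent time-invariant driving pressure of a cycle
#'
#' Inverts the closed-form Kelvin impulse to obtain the constant driving
#' pressure that would reproduce the virtual impulse `I_hat` measured
#' under a known constant gradient:
#' `dp_bar = (4.789 R0^4 grad_hat sqrt(rho_l) / I_hat)^2`.
#'
#' @param R0_cycle Largest radius reached within the cycle (m).
#' @param I_hat Virtual Kelvin impulse under the gradient `grad_hat`
#'   (kg m s^-1); must be non-zero.
#' @param med A [medium()].
#' @param grad_hat The constant gradient used for the virtual impulse
#'   (Pa m^-1), default unitary.
#' @return Equivalent driving pressure (Pa).
#' @export
equivalent_dp <- function(R0_cycle, I_hat, med, grad_hat = 1) {
  if (any(I_hat == 0))
    stop("virtual impulse is zero; equivalent pressure undefined")
  C <- RAYLEIGH_PREFACTOR_ANALYTIC()
  (C * R0_cycle^4 * grad_hat * sqrt(med$rho_l) / I_hat)^2
}

#' Per-cycle Kelvin impulses and jet anisotropy parameters
#'
#' Decomposes the Kelvin impulse acquired by the fluid in every
#' ultrasound cycle into the contribution of the travelling-wave
#' pressure gradient (`I_us`) and of the rigid substrate's mirror-bubble
#' sound field (`I_sub`, with
#' `grad p_sub = rho_l Vddot / (16 pi (L - x)^2)` so that
#' `F_B2 = -V grad p_sub`). Cycle windows are delimited by the upward
#' zero crossings of the carrier. For each cycle the equivalent
#' time-invariant driving pressure `dp_bar` is obtained from the virtual
#' impulse under a unit gradient, and the anisotropy parameters follow
#' from `zeta = I / (4.789 R0_cycle^3 sqrt(rho_l dp_bar))`.
#'
#' @param radial A [solve_radial()] result.
#' @param translation A [solve_translation()] result on the same grid
#'   (it may end early at tunnel contact; only the full cycles it covers
#'   are reported).
#' @param pulse,med,cell Model objects; defaults from the solutions.
#' @return Data frame with one row per full cycle: `cycle`, `t_start`,
#'   `t_end`, `R0_cycle`, `I_us`, `I_sub`, `I_total`, `I_hat`, `dp_bar`,
#'   `zeta_us`, `zeta_sub`, `zeta_total` and `ratio_sub_us`
#'   (= `|I_sub/I_us|`).
#' @export
cycle_impulses <- function(radial, translation, pulse = radial$pulse,
                           med = radial$med, cell = translation$cell) {
  f <- pulse$f
  t <- translation$t
  n_full <- floor((max(t) + radial$tau / 2) * f)
  n_full <- min(n_full, pulse$n_cycles)
  if (n_full < 1)
    stop("solutions cover less than one full ultrasound cycle")
  V <- radial$V[seq_along(t)]
  gus <- pulse_gradient(pulse, med, t)
  gsub <- med$rho_l * radial$Vddot[seq_along(t)] /
    (16 * pi * (cell$L - translation$x)^2)
  C <- RAYLEIGH_PREFACTOR_ANALYTIC()
  rows <- lapply(seq_len(n_full), function(n) {
    w <- c((n - 1) / f, n / f)
    idx <- t >= w[1] - radial$tau / 2 & t <= w[2] + radial$tau / 2
    tt <- t[idx]
    R0c <- max(radial$R[seq_along(t)][idx])
    I_us <- -trapz(tt, V[idx] * gus[idx])
    I_sub <- -trapz(tt, V[idx] * gsub[idx])
    I_hat <- -trapz(tt, V[idx])  # unit gradient
    dp_bar <- (C * R0c^4 * sqrt(med$rho_l) / I_hat)^2
    denom <- C * R0c^3 * sqrt(med$rho_l * dp_bar)
    data.frame(cycle = n, t_start = w[1], t_end = w[2], R0_cycle = R0c,
               I_us = I_us, I_sub = I_sub, I_total = I_us + I_sub,
               I_hat = I_hat, dp_bar = dp_bar,
               zeta_us = I_us / denom, zeta_sub = I_sub / denom,
               zeta_total = (I_us + I_sub) / denom,
               ratio_sub_us = abs(I_sub / I_us))
  })
  do.call(rbind, rows)
}
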