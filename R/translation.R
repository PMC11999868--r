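#' Fractional-viscoelastic cell layer
#'
#' A single spring-pot (fractional element) characterizes the cell
#' rheology at the very high strain rates (1e5-1e7 s^-1) of bubble-driven
#' deformation: its stress is `c_beta` times the Caputo derivative of
#' order `beta` of the compressive strain `x/L`. `beta = 0` recovers a
#' spring, `beta = 1` a dashpot.
#'
#' @param L Initial cell-layer thickness (m).
#' @param beta Fractional order in (0, 1).
#' @param c_beta Spring-pot coefficient (Pa s^beta).
#' @return An object of class `cell_layer`.
#' @export
cell_layer <- function(L = 12e-6, beta = 0.8, c_beta = 1) {
  if (!is.finite(L) || L <= 0) stop("cell thickness L must be positive")
  if (!is.finite(beta) || beta <= 0 || beta >= 1)
    stop("fractional order beta must lie strictly between 0 and 1")
  if (!is.finite(c_beta) || c_beta <= 0) stop("c_beta must be positive")
  structure(list(L = L, beta = beta, c_beta = c_beta),
            class = "cell_layer")
}

#' L1 discretization of the Caputo fractional derivative
#'
#' Computes the Caputo derivative of order `beta` in (0, 1) of a signal
#' sampled on a uniform grid, using the standard L1 scheme with weights
#' `b_(k-j) = (k-j+1)^(1-beta) - (k-j)^(1-beta)`:
#' `D^beta eps(t_k) = tau^(-beta)/Gamma(2-beta) *
#'   sum_j b_(k-j) (eps_j - eps_(j-1))`.
#' The scheme is exact for linear signals and converges at order
#' `tau^(2-beta)` for smooth ones.
#'
#' @param eps Samples of the signal on a uniform grid starting at `t = 0`
#'   (the first element is the initial value).
#' @param beta Fractional order in (0, 1).
#' @param tau Grid step (s).
#' @return Numeric vector of the same length as `eps`; the first element
#'   is 0.
#' @examples
#' tt <- seq(0, 1, by = 1e-3)
#' d <- caputo_l1(tt, beta = 0.8, tau = 1e-3)
#' # closed form: t^0.2 / gamma(1.2)
#' max(abs(d[-1] - tt[-1]^0.2 / gamma(1.2)))
#' @export
caputo_l1 <- function(eps, beta, tau) {
  if (beta <= 0 || beta >= 1) stop("beta must lie strictly in (0, 1)")
  if (tau <= 0) stop("grid step tau must be positive")
  n <- length(eps)
  if (n < 2) return(rep(0, n))
  d_eps <- diff(eps)
  i <- seq_len(n - 1)
  b <- i^(1 - beta) - (i - 1)^(1 - beta)  # b[1] = b_0 = 1
  out <- numeric(n)
  for (k in seq_len(n - 1)) {
    out[k + 1] <- sum(b[k:1] * d_eps[seq_len(k)])
  }
  out * tau^(-beta) / gamma(2 - beta)
}

#' Drag coefficient of a translating bubble
#'
#' Empirical correlation `C_D = 24/Re + 6/(1 + sqrt(Re)) + 0.4`,
#' positive and strictly decreasing; the `24/Re` term recovers Stokes
#' drag in the creeping-flow limit and the constant the high-Reynolds
#' plateau.
#'
#' @param Re Instantaneous translational Reynolds number, positive.
#' @return Drag coefficient (unitless), vectorized.
#' @examples
#' drag_coefficient(1) # 24 + 3 + 0.4
#' @export
drag_coefficient <- function(Re) {
  if (any(Re <= 0)) stop("Re must be positive; the Re -> 0 limit is
handled inside the drag force term")
  24 / Re + 6 / (1 + sqrt(Re)) + 0.4
}

## viscous drag force with the Stokes part split off analytically so the
## xdot -> 0 limit is regular: 1/2 rho pi R^2 (24/Re) xdot|xdot| =
## 6 pi mu R xdot
drag_force <- function(R, xdot, med) {
  Re <- 2 * med$rho_l * R * abs(xdot) / med$mu_l
  -6 * pi * med$mu_l * R * xdot -
    0.5 * med$rho_l * pi * R^2 * (6 / (1 + sqrt(Re)) + 0.4) * xdot * abs(xdot)
}

#' Force terms of the translational balance at one instant
#'
#' Evaluates the six force channels acting on the bubble at time `t`,
#' interpolating the radial solution: inertial force `F_I = m xddot`,
#' primary Bjerknes force `F_B1 = -V dp_d/dx`, secondary Bjerknes force
#' from the rigid substrate (mirror bubble)
#' `F_B2 = -rho_l V Vddot / (16 pi (L - x)^2)`, added-mass force
#' `F_AM = -1/2 rho_l (Vdot xdot + V xddot)`, quasi-steady drag `F_VD`
#' (opposing motion) and cell resistive force
#' `F_CR = -pi R^2 c_beta D^beta eps`.
#'
#' @param radial A [solve_radial()] result.
#' @param state Numeric `c(x, xdot)`: centroid displacement towards the
#'   substrate (m) and its rate (m s^-1).
#' @param t Time (s).
#' @param pulse,med,cell Model objects.
#' @param xddot Centroid acceleration (m s^-2) entering `F_I` and
#'   `F_AM`; defaults to 0.
#' @param caputo_eps Value of the Caputo derivative of the strain at
#'   `t` (s^-beta); defaults to 0 (e.g. for a bubble at rest).
#' @return Named list of forces (N) plus the instantaneous Reynolds
#'   number `Re` and velocity ratio `U = Rdot/xdot`.
#' @export
force_terms <- function(radial, state, t, pulse, med, cell, xddot = 0,
                        caputo_eps = 0) {
  x <- state[1]; xdot <- state[2]
  if (x >= cell$L)
    stop("geometric violation: bubble centroid has reached the substrate")
  R <- approx(radial$t, radial$R, t, rule = 2)$y
  Rd <- approx(radial$t, radial$Rdot, t, rule = 2)$y
  V <- approx(radial$t, radial$V, t, rule = 2)$y
  Vd <- approx(radial$t, radial$Vdot, t, rule = 2)$y
  Vdd <- approx(radial$t, radial$Vddot, t, rule = 2)$y
  m <- radial$bubble$rho_g * radial$V[1]
  F_B1 <- -V * pulse_gradient(pulse, med, t)
  F_B2 <- -med$rho_l * V * Vdd / (16 * pi * (cell$L - x)^2)
  F_VD <- drag_force(R, xdot, med)
  F_CR <- -pi * R^2 * cell$c_beta * caputo_eps
  F_AM <- -0.5 * med$rho_l * (Vd * xdot + V * xddot)
  list(F_I = m * xddot, F_B1 = F_B1, F_B2 = F_B2, F_AM = F_AM,
       F_VD = F_VD, F_CR = F_CR, m = m,
       Re = 2 * med$rho_l * R * abs(xdot) / med$mu_l,
       U = if (xdot != 0) Rd / xdot else NA_real_)
}

#' Solve the translational dynamics of a bubble pressing into the cell
#'
#' Integrates the force balance
#' `F_I = F_B1 + F_B2 + F_AM + F_VD + F_CR` on the uniform grid of the
#' radial solution, with the cell resistive force carrying the full
#' L1-Caputo strain history. The added-mass force is taken as the time
#' derivative of the added-mass momentum,
#' `F_AM = -d/dt[1/2 rho_l V xdot]`, so the `xddot` contributions of
#' `F_I` and `F_AM` are collected on the left-hand side before
#' inversion; `added_mass = "as_printed"` instead uses
#' `-1/2 rho_l (Vdot x + V xdot)` verbatim (dimensionally a momentum;
#' retained for comparison only). Each step solves the implicit
#' trapezoidal update with a Newton iteration, which keeps the stiff
#' secondary-Bjerknes kicks at bubble collapse stable.
#'
#' If the centroid reaches the substrate (`x -> L`, the cell's ultimate
#' compression; a transendothelial tunnel in the experiments) the
#' integration stops and the event is flagged.
#'
#' @param radial A [solve_radial()] result (uniform grid).
#' @param pulse,med,cell Model objects; defaults taken from `radial`
#'   where available.
#' @param added_mass `"derivative"` (default) or `"as_printed"`.
#' @param contact_frac Fraction of `L` treated as contact (default
#'   0.999).
#'
#' @return An object of class `translation_solution`: time grid `t`
#'   (truncated at contact if it occurs), displacement `x`, velocity
#'   `xdot`, acceleration `xddot`, strain `eps = x/L`, a `forces` data
#'   frame with the six per-term series, diagnostics `Re_mean` and
#'   `URe_mean` (time averages over the pulse), and `contact`
#'   (list with `occurred`, `time`).
#' @export
solve_translation <- function(radial, pulse = radial$pulse,
                              med = radial$med, cell = cell_layer(),
                              added_mass = c("derivative", "as_printed"),
                              contact_frac = 0.999) {
  added_mass <- match.arg(added_mass)
  times <- radial$t
  tau <- radial$tau
  if (max(abs(diff(times) - tau)) > 1e-6 * tau)
    stop("radial solution must be on a uniform grid")
  N <- length(times)
  R <- radial$R; V <- radial$V; Vd <- radial$Vdot; Vdd <- radial$Vddot
  gus <- pulse_gradient(pulse, med, times)
  rho <- med$rho_l; L <- cell$L; beta <- cell$beta
  gam <- gamma(2 - beta)
  i <- seq_len(N)
  bw <- i^(1 - beta) - (i - 1)^(1 - beta)
  m0 <- radial$bubble$rho_g * V[1]

  x <- numeric(N); v <- numeric(N); a <- numeric(N); deps <- numeric(N)
  FB1s <- -V * gus
  accel_at <- function(k, xk, vk, Dbeta) {
    F_B2 <- -rho * V[k] * Vdd[k] / (16 * pi * (L - xk)^2)
    F_VD <- drag_force(R[k], vk, med)
    F_CR <- -pi * R[k]^2 * cell$c_beta * Dbeta
    if (added_mass == "derivative") {
      (FB1s[k] + F_B2 + F_VD + F_CR - 0.5 * rho * Vd[k] * vk) /
        (m0 + 0.5 * rho * V[k])
    } else {
      F_AM <- -0.5 * rho * (Vd[k] * xk + V[k] * vk)
      (FB1s[k] + F_B2 + F_VD + F_CR + F_AM) / m0
    }
  }
  contact_k <- NA_integer_
  for (k in 2:N) {
    hist_sum <- if (k > 2) sum(bw[(k - 1):2] * deps[2:(k - 1)]) else 0
    g <- function(ak) {
      vk <- v[k - 1] + 0.5 * tau * (a[k - 1] + ak)
      xk <- x[k - 1] + 0.5 * tau * (v[k - 1] + vk)
      if (xk >= L * contact_frac) return(NA_real_)
      Dbeta <- tau^(-beta) / gam *
        (hist_sum + bw[1] * (xk - x[k - 1]) / L)
      ak - accel_at(k, xk, vk, Dbeta)
    }
    ak <- a[k - 1]
    converged <- FALSE
    for (it in 1:60) {
      g0 <- g(ak)
      if (is.na(g0)) break
      da <- max(abs(ak) * 1e-7, 1)
      g1 <- g(ak + da)
      if (is.na(g1)) break
      slope <- (g1 - g0) / da
      if (!is.finite(slope) || slope == 0) break
      step <- g0 / slope
      ak <- ak - step
      if (abs(step) <= 1e-9 * max(abs(ak), 1)) { converged <- TRUE; break }
    }
    if (!converged || is.na(g(ak))) { contact_k <- k; break }
    a[k] <- ak
    v[k] <- v[k - 1] + 0.5 * tau * (a[k - 1] + ak)
    x[k] <- x[k - 1] + 0.5 * tau * (v[k - 1] + v[k])
    deps[k] <- (x[k] - x[k - 1]) / L
    if (x[k] >= L * contact_frac) { contact_k <- k; break }
  }
  Nv <- if (is.na(contact_k)) N else contact_k - 1L
  idx <- seq_len(Nv)
  Dbeta_series <- caputo_l1(x[idx] / L, beta, tau)
  F_B2 <- -rho * V[idx] * Vdd[idx] / (16 * pi * (L - x[idx])^2)
  F_VD <- drag_force(R[idx], v[idx], med)
  F_CR <- -pi * R[idx]^2 * cell$c_beta * Dbeta_series
  F_AM <- -0.5 * rho * (Vd[idx] * v[idx] + V[idx] * a[idx])
  m_series <- rep(m0, Nv)
  forces <- data.frame(t = times[idx], F_I = m_series * a[idx],
                       F_B1 = FB1s[idx], F_B2 = F_B2, F_AM = F_AM,
                       F_VD = F_VD, F_CR = F_CR)
  in_pulse <- times[idx] <= pulse$duration
  Re_s <- 2 * rho * R[idx] * abs(v[idx]) / med$mu_l
  URe_s <- 2 * rho * R[idx] * abs(radial$Rdot[idx]) / med$mu_l
  structure(list(t = times[idx], x = x[idx], xdot = v[idx],
                 xddot = a[idx], eps = x[idx] / L,
                 caputo_eps = Dbeta_series, forces = forces,
                 Re_mean = mean(Re_s[in_pulse]),
                 URe_mean = mean(URe_s[in_pulse]),
                 contact = list(occurred = !is.na(contact_k),
                                time = if (is.na(contact_k)) NA_real_
                                       else times[contact_k]),
                 cell = cell, added_mass = added_mass),
            class = "translation_solution")
}

#' @export
print.translation_solution <- function(x, ...) {
  cat(sprintf(
    "translation solution: %d samples, x_max = %.3g um (eps_max = %.3g)\n",
    length(x$t), max(x$x) * 1e6, max(x$eps)))
  if (x$contact$occurred)
    cat(sprintf("  ultimate compression (tunnel contact) at t = %.3g us\n",
                x$contact$time * 1e6))
  cat(sprintf("  mean Re = %.3g, mean U*Re = %.3g\n", x$Re_mean,
              x$URe_mean))
  invisible(x)
}
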