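#' Jet parameters
#'
#' Speed and head radius of a microjet. The default speed is the lower
#' bound implied by a jet traversing the bubble within a single
#' high-speed-camera frame; the head radius defaults to a quarter of the
#' equilibrium bubble radius of the reference case (3 um), i.e. 0.75 um.
#'
#' @param u_jet Jet speed (m s^-1), positive.
#' @param R_jet Jet head radius (m), positive.
#' @return An object of class `jet_params`.
#' @export
jet_params <- function(u_jet = 60, R_jet = 0.75e-6) {
  if (!is.finite(u_jet) || u_jet < 0) stop("u_jet must be non-negative")
  if (!is.finite(R_jet) || R_jet < 0) stop("R_jet must be non-negative")
  structure(list(u_jet = u_jet, R_jet = R_jet), class = "jet_params")
}

#' Lower bound on the jet speed from frame-rate crossing
#'
#' A jet observed to traverse the whole bubble (diameter `2 R0`) within
#' one camera frame must travel at least `2 R0 / frame_dt`.
#'
#' @param R0 Bubble equilibrium radius (m).
#' @param frame_dt Frame interval (s); default 0.1 us (10 Mfps).
#' @return Minimum jet speed (m s^-1).
#' @examples
#' min_jet_speed(3e-6) # 60 m/s
#' @export
min_jet_speed <- function(R0, frame_dt = 1e-7) 2 * R0 / frame_dt

#' Jet impact stresses and contact geometry
#'
#' Water-hammer pressure `p_jet = 1/2 rho_l c_l u_jet`, Bernoulli
#' stagnation pressure `p_stag = 1/2 rho_l u_jet^2`, contact radius
#' `rho_contact = R_jet u_jet / c_l` and hammer duration
#' `varsigma = R_jet u_jet / c_l^2` (the transit time of the rarefaction
#' wave from the contact edge, so `varsigma = rho_contact / c_l`).
#'
#' @param jet A [jet_params()].
#' @param med A [medium()].
#' @return List with `p_jet` (Pa), `p_stag` (Pa), `rho_contact` (m) and
#'   `varsigma` (s).
#' @examples
#' jet_stresses(jet_params(u_jet = 60), medium())
#' @export
jet_stresses <- function(jet, med) {
  list(p_jet = 0.5 * med$rho_l * med$c_l * jet$u_jet,
       p_stag = 0.5 * med$rho_l * jet$u_jet^2,
       rho_contact = jet$R_jet * jet$u_jet / med$c_l,
       varsigma = jet$R_jet * jet$u_jet / med$c_l^2)
}

## resample a radial solution's R (and optionally x) to an observation
## grid; NULL rate keeps the native grid
resample_radius <- function(radial, sample_rate = NULL, x = NULL,
                            t_trans = NULL) {
  if (is.null(sample_rate)) {
    tt <- if (is.null(x)) radial$t else t_trans
    idx <- seq_along(tt)
    return(list(t = tt, R = radial$R[idx],
                x = if (is.null(x)) rep(0, length(tt)) else x))
  }
  t_max <- if (is.null(x)) max(radial$t) else max(t_trans)
  tt <- seq(0, t_max, by = 1 / sample_rate)
  list(t = tt,
       R = approx(radial$t, radial$R, tt, rule = 2)$y,
       x = if (is.null(x)) rep(0, length(tt))
           else approx(t_trans, x, tt, rule = 2)$y)
}

## centered finite differences on a uniform grid (one-sided at the ends)
fd1 <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}
fd2 <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]) / dt^2
  d
}

#' Oscillatory-flow stresses on the cell
#'
#' Bernoulli impact/suction pressure `p_impact = 1/2 rho_l |Rdot| Rdot`
#' (signed), oscillatory viscous shear `tau_shear = mu_l Rdot / delta`,
#' acoustic-streaming shear `tau_stream = mu_l u_stream / delta`, with
#' the oscillatory boundary-layer thickness
#' `delta = sqrt(2 mu_l / (rho_l omega))`.
#'
#' Wall velocities are, by default, obtained by finite differences of
#' the radius resampled at the high-speed-camera frame rate (10 Mfps),
#' matching how these stresses are inferred from observed bubble motion;
#' pass `sample_rate = NULL` to differentiate the native solver grid.
#'
#' @param radial A [solve_radial()] result.
#' @param pulse,med Model objects; defaults from `radial`.
#' @param u_stream Streaming speed bound (m s^-1).
#' @param sample_rate Observation sampling rate (s^-1) or NULL.
#' @return List with the series `t`, `p_impact`, `tau_shear`, scalar
#'   `tau_stream` and `delta`.
#' @export
flow_stresses <- function(radial, pulse = radial$pulse, med = radial$med,
                          u_stream = 0.1, sample_rate = 1e7) {
  om <- 2 * pi * pulse$f
  if (om <= 0) stop("pulse frequency must be positive to define the
boundary layer")
  if (u_stream < 0) stop("u_stream must be non-negative")
  delta <- sqrt(2 * med$mu_l / (med$rho_l * om))
  rs <- resample_radius(radial, sample_rate)
  dt <- rs$t[2] - rs$t[1]
  Rd <- fd1(rs$R, dt)
  list(t = rs$t,
       p_impact = 0.5 * med$rho_l * abs(Rd) * Rd,
       tau_shear = med$mu_l * Rd / delta,
       tau_stream = med$mu_l * u_stream / delta,
       delta = delta)
}

#' Bjerknes cross-section pressures
#'
#' Average pressures exerted on the bubble cross-section by the primary
#' and secondary Bjerknes forces:
#' `p_B1 = -(4/3) R dp_d/dx` and
#' `p_B2 = -rho_l R Vddot / (12 pi h^2)`, where `h` is the
#' bubble-substrate distance.
#'
#' @param radial A [solve_radial()] result.
#' @param pulse,med Model objects; defaults from `radial`.
#' @param h Bubble-substrate distance series (m) on the evaluation grid
#'   (or a scalar); must be positive.
#' @param sample_rate Observation sampling rate (s^-1) or NULL for the
#'   native grid (see [flow_stresses()]).
#' @param t_eval Optional evaluation grid; defaults to the resampled
#'   grid.
#' @return List with `t`, `p_B1`, `p_B2` (Pa, signed).
#' @export
bjerknes_pressures <- function(radial, pulse = radial$pulse,
                               med = radial$med, h, sample_rate = 1e7,
                               t_eval = NULL) {
  if (any(h <= 0)) stop("bubble-substrate distance h must be positive")
  rs <- resample_radius(radial, sample_rate)
  tt <- if (is.null(t_eval)) rs$t else t_eval
  R <- approx(rs$t, rs$R, tt, rule = 2)$y
  dt <- rs$t[2] - rs$t[1]
  Vdd <- approx(rs$t, fd2(4 / 3 * pi * rs$R^3, dt), tt, rule = 2)$y
  if (length(h) == 1) h <- rep(h, length(tt))
  if (length(h) != length(tt))
    stop("h must be scalar or match the evaluation grid")
  list(t = tt,
       p_B1 = -4 / 3 * R * pulse_gradient(pulse, med, tt),
       p_B2 = -med$rho_l * R * Vdd / (12 * pi * h^2))
}

#' Stress comparison across damage mechanisms
#'
#' Assembles all modeled stress channels on a common observation grid
#' and reports the peak magnitude of each mechanism together with the
#' ratio of the water-hammer pressure to every other peak. The
#' water-hammer pressure is an event channel: it acts at the
#' compression-phase peaks of the driving pressure once the radial
#' expansion has first exceeded the jetting threshold, and is zero
#' elsewhere.
#'
#' @param radial A [solve_radial()] result.
#' @param translation Optional [solve_translation()] result; when given,
#'   the bubble-substrate distance is `h = L - x(t)` (frozen at its last
#'   value after tunnel contact), otherwise `h = L`.
#' @param pulse,med Model objects; defaults from `radial`.
#' @param jet A [jet_params()].
#' @param u_stream Streaming speed bound (m s^-1).
#' @param sample_rate Observation sampling rate (s^-1); NULL for the
#'   native solver grid.
#' @param jet_threshold Radial-expansion threshold (m) gating the jet
#'   events.
#' @param cell A [cell_layer()]; used for `h` when `translation` is
#'   missing.
#' @return An object of class `stress_report`: list with `series` (data
#'   frame of all channels vs time), `peaks` (data frame `mechanism`,
#'   `peak`, `ratio_jet_to_peak`), the scalars of [jet_stresses()], and
#'   `jet_times`.
#' @export
stress_report <- function(radial, translation = NULL,
                          pulse = radial$pulse, med = radial$med,
                          jet = jet_params(), u_stream = 0.1,
                          sample_rate = 1e7, jet_threshold = 1e-6,
                          cell = cell_layer()) {
  js <- jet_stresses(jet, med)
  fs <- flow_stresses(radial, pulse, med, u_stream, sample_rate)
  tt <- fs$t
  if (!is.null(translation)) {
    cell <- translation$cell
    ## after tunnel contact the mirror-image description of the
    ## substrate no longer applies: stop the comparison there
    if (translation$contact$occurred) {
      keep <- tt <= translation$contact$time
      tt <- tt[keep]
      fs$t <- tt
      fs$p_impact <- fs$p_impact[keep]
      fs$tau_shear <- fs$tau_shear[keep]
    }
    x_t <- approx(translation$t, translation$x, tt, rule = 2)$y
    R_t <- approx(radial$t, radial$R, tt, rule = 2)$y
    ## the point-mirror approximation behind p_B2 holds for distances
    ## of at least a bubble radius; floor h at R(t)
    h <- pmax(cell$L - x_t, R_t)
  } else {
    h <- rep(cell$L, length(tt))
  }
  bp <- bjerknes_pressures(radial, pulse, med, h, sample_rate,
                           t_eval = tt)
  ## jet events: compression peaks of p_d after the expansion threshold
  ## is first exceeded
  exp_series <- approx(radial$t, radial$R, tt, rule = 2)$y -
    radial$bubble$R0
  first_jet <- which(exp_series >= jet_threshold)[1]
  p_jet_series <- numeric(length(tt))
  jet_times <- numeric(0)
  if (!is.na(first_jet) && pulse$p_a > 0) {
    f <- pulse$f
    t_first <- tt[first_jet]
    ## compression peaks of the carrier: p_d maximal at phase pi/2
    n_all <- seq_len(pulse$n_cycles)
    t_peaks <- (n_all - 1 + 0.25) / f
    t_peaks <- t_peaks[t_peaks >= t_first & t_peaks <= max(tt)]
    if (length(t_peaks) > 0) {
      k <- vapply(t_peaks, function(tp) which.min(abs(tt - tp)),
                  integer(1))
      p_jet_series[k] <- js$p_jet
      jet_times <- tt[k]
    }
  }
  series <- data.frame(t = tt, p_jet = p_jet_series,
                       p_stag = ifelse(p_jet_series > 0, js$p_stag, 0),
                       p_impact = fs$p_impact, tau_shear = fs$tau_shear,
                       tau_stream = rep(fs$tau_stream, length(tt)),
                       p_B1 = bp$p_B1, p_B2 = bp$p_B2)
  others <- c(p_impact = max(abs(fs$p_impact)),
              tau_shear = max(abs(fs$tau_shear)),
              tau_stream = fs$tau_stream,
              p_B1 = max(abs(bp$p_B1)),
              p_B2 = max(abs(bp$p_B2)))
  peaks <- data.frame(mechanism = c("p_jet", "p_stag", names(others)),
                      peak = c(js$p_jet, js$p_stag, unname(others)),
                      ratio_jet_to_peak =
                        c(1, js$p_jet / js$p_stag,
                          unname(js$p_jet / others)))
  structure(c(js, list(series = series, peaks = peaks,
                       jet_times = jet_times, delta = fs$delta,
                       sample_rate = sample_rate)),
            class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  cat("stress comparison (peak magnitudes):\n")
  pk <- x$peaks
  for (i in seq_len(nrow(pk)))
    cat(sprintf("  %-10s %10.4g Pa   (p_jet / peak = %.3g)\n",
                pk$mechanism[i], pk$peak[i], pk$ratio_jet_to_peak[i]))
  invisible(x)
}
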