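#' Ambient liquid medium
#'
#' Container for the physical properties of the liquid surrounding the
#' bubble. Defaults describe degassed water near room temperature, the
#' standard bath in sonoporation experiments.
#'
#' @param rho_l Liquid density (kg m^-3).
#' @param mu_l Dynamic viscosity (Pa s).
#' @param c_l Speed of sound (m s^-1).
#' @param p0 Ambient static pressure (Pa).
#' @param p_v Vapour pressure (Pa).
#' @param sigma_w Clean gas-water surface tension (N m^-1).
#' @param T_l Temperature (degrees C, metadata only; not used in any
#'   formula).
#'
#' @return An object of class `medium`.
#' @examples
#' med <- medium()
#' med$rho_l
#' @export
medium <- function(rho_l = 998, mu_l = 1e-3, c_l = 1482, p0 = 101325,
                   p_v = 2645, sigma_w = 0.072, T_l = 22) {
  vals <- c(rho_l = rho_l, mu_l = mu_l, c_l = c_l, p0 = p0, p_v = p_v,
            sigma_w = sigma_w)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all medium properties must be strictly positive and finite")
  if (p0 <= p_v)
    stop("ambient pressure p0 must exceed the vapour pressure p_v")
  structure(list(rho_l = rho_l, mu_l = mu_l, c_l = c_l, p0 = p0,
                 p_v = p_v, sigma_w = sigma_w, T_l = T_l),
            class = "medium")
}

#' Driving ultrasound pulse
#'
#' Builds a finite ultrasound pulse `p_d(t) = p_a * env(t) * sin(2 pi f t)`.
#' The envelope is either the default parametric ramp (linear rise over
#' `ramp_cycles` carrier cycles, then constant at 1) or a sampled envelope
#' table such as a hydrophone recording. Outside the pulse window
#' `[0, n_cycles/f]` the pressure is exactly zero.
#'
#' @param f Carrier frequency (Hz).
#' @param p_a Peak pressure amplitude (Pa), non-negative.
#' @param n_cycles Number of carrier cycles (>= 1).
#' @param ramp_cycles Length of the linear amplitude ramp in carrier
#'   cycles; 0 gives a rectangular envelope. Ignored when `envelope` is
#'   supplied.
#' @param angle_deg Angle (degrees) between the propagation direction and
#'   the substrate normal; pressure-gradient projections use
#'   `cos(angle_deg)`. The default 15 degrees corresponds to a transducer
#'   insonifying at 75 degrees from the horizontal plane with the
#'   substrate normal vertical.
#' @param envelope Optional sampled envelope: a data frame with columns
#'   `time_s` (strictly increasing, covering `[0, n_cycles/f]`) and
#'   `amplitude` (in `[0, 1]`, starting at 0). Values between samples are
#'   linearly interpolated.
#'
#' @return An object of class `ultrasound_pulse`.
#' @examples
#' pu <- ultrasound_pulse(f = 1e6, p_a = 160e3, n_cycles = 20)
#' pulse_duration(pu) # 20 microseconds
#' @export
ultrasound_pulse <- function(f = 1e6, p_a, n_cycles = 20, ramp_cycles = 5,
                             angle_deg = 15, envelope = NULL) {
  if (!is.finite(f) || f <= 0) stop("carrier frequency f must be positive")
  if (!is.finite(p_a) || p_a < 0) stop("pressure amplitude p_a must be non-negative")
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  if (ramp_cycles < 0) stop("ramp_cycles must be non-negative")
  duration <- n_cycles / f
  if (!is.null(envelope)) {
    if (!all(c("time_s", "amplitude") %in% names(envelope)))
      stop("sampled envelope needs columns 'time_s' and 'amplitude'")
    tt <- envelope$time_s
    aa <- envelope$amplitude
    if (any(diff(tt) <= 0))
      stop("envelope time axis must be strictly increasing")
    if (min(tt) > 0 || max(tt) < duration)
      stop("sampled envelope must cover the pulse window [0, n_cycles/f]")
    if (any(aa < -1e-12) || any(aa > 1 + 1e-12))
      stop("envelope amplitudes must lie in [0, 1]")
    if (abs(aa[1]) > 1e-9 && tt[1] <= 0)
      stop("envelope must start at amplitude 0")
  }
  structure(list(f = f, p_a = p_a, n_cycles = n_cycles,
                 ramp_cycles = ramp_cycles, angle_deg = angle_deg,
                 envelope = envelope, duration = duration),
            class = "ultrasound_pulse")
}

#' Pulse duration
#' @param pulse An [ultrasound_pulse()].
#' @return Duration `n_cycles / f` in seconds.
#' @export
pulse_duration <- function(pulse) pulse$duration

#' Normalized pulse envelope
#'
#' Evaluates the unitless envelope on `[0, 1]`; exactly 0 outside the
#' pulse window.
#'
#' @param pulse An [ultrasound_pulse()].
#' @param t Time (s), vectorized.
#' @return Envelope values in `[0, 1]`.
#' @export
pulse_envelope <- function(pulse, t) {
  inside <- t >= 0 & t <= pulse$duration
  if (is.null(pulse$envelope)) {
    if (pulse$ramp_cycles == 0) {
      env <- as.numeric(inside)
    } else {
      env <- pmin(pmax(t * pulse$f / pulse$ramp_cycles, 0), 1)
      env[!inside] <- 0
    }
  } else {
    env <- approx(pulse$envelope$time_s, pulse$envelope$amplitude,
                  xout = t, rule = 2)$y
    env[!inside] <- 0
  }
  env
}

#' Driving pressure of the pulse
#'
#' @param pulse An [ultrasound_pulse()].
#' @param t Time (s), vectorized.
#' @return `p_d(t) = p_a * env(t) * sin(2 pi f t)` in Pa; 0 outside the
#'   pulse window.
#' @export
pulse_pressure <- function(pulse, t) {
  pulse$p_a * pulse_envelope(pulse, t) * sin(2 * pi * pulse$f * t)
}

## time derivative of p_d; envelope slope handled analytically for the
## parametric ramp and by a small centered difference for sampled tables
pulse_pressure_dot <- function(pulse, t) {
  om <- 2 * pi * pulse$f
  env <- pulse_envelope(pulse, t)
  inside <- t >= 0 & t <= pulse$duration
  if (is.null(pulse$envelope)) {
    denv <- ifelse(inside & pulse$ramp_cycles > 0 &
                     t < pulse$ramp_cycles / pulse$f,
                   pulse$f / pulse$ramp_cycles, 0)
  } else {
    dt <- 1 / (1000 * pulse$f)
    denv <- (pulse_envelope(pulse, t + dt) - pulse_envelope(pulse, t - dt)) /
      (2 * dt)
    denv[!inside] <- 0
  }
  pulse$p_a * (denv * sin(om * t) + env * om * cos(om * t))
}

## scalar fast paths used inside ODE right-hand sides, where the
## vectorized evaluators dominate the runtime
scalar_pd <- function(pulse) {
  f <- pulse$f; p_a <- pulse$p_a; dur <- pulse$duration
  om <- 2 * pi * f
  if (is.null(pulse$envelope)) {
    rc <- pulse$ramp_cycles
    if (rc == 0) {
      function(t) if (t <= 0 || t > dur) 0 else p_a * sin(om * t)
    } else {
      tr <- rc / f
      function(t) {
        if (t <= 0 || t > dur) return(0)
        e <- if (t < tr) t / tr else 1
        p_a * e * sin(om * t)
      }
    }
  } else {
    ef <- stats::approxfun(pulse$envelope$time_s,
                           pulse$envelope$amplitude, rule = 2)
    function(t) if (t <= 0 || t > dur) 0 else p_a * ef(t) * sin(om * t)
  }
}

scalar_pd_dot <- function(pulse) {
  f <- pulse$f; p_a <- pulse$p_a; dur <- pulse$duration
  om <- 2 * pi * f
  if (is.null(pulse$envelope)) {
    rc <- pulse$ramp_cycles
    tr <- if (rc > 0) rc / f else 0
    function(t) {
      if (t <= 0 || t > dur) return(0)
      if (rc > 0 && t < tr)
        p_a * (sin(om * t) / tr + (t / tr) * om * cos(om * t))
      else p_a * om * cos(om * t)
    }
  } else {
    ef <- stats::approxfun(pulse$envelope$time_s,
                           pulse$envelope$amplitude, rule = 2)
    dt <- 1 / (1000 * f)
    function(t) {
      if (t <= 0 || t > dur) return(0)
      e <- ef(t)
      de <- (ef(min(t + dt, dur)) - ef(max(t - dt, 0))) /
        (min(t + dt, dur) - max(t - dt, 0))
      p_a * (de * sin(om * t) + e * om * cos(om * t))
    }
  }
}

#' Spatial pressure gradient of the travelling pulse
#'
#' Plane travelling-wave closure: for a wave propagating towards the
#' substrate, `dp/dx = -(1/c_l) dp/dt` along the propagation direction.
#' The component along the substrate normal is obtained by projecting
#' with `cos(angle_deg)`.
#'
#' @param pulse An [ultrasound_pulse()].
#' @param med A [medium()].
#' @param t Time (s), vectorized.
#' @return Signed gradient (Pa m^-1) along the substrate normal (positive
#'   towards the substrate).
#' @export
pulse_gradient <- function(pulse, med, t) {
  -cos(pulse$angle_deg * pi / 180) / med$c_l * pulse_pressure_dot(pulse, t)
}

#' Evaluate driving pressure and gradient on a time grid
#'
#' @param pulse An [ultrasound_pulse()].
#' @param med A [medium()].
#' @param t Time grid (s).
#' @return Data frame with columns `t`, `p_d` (Pa) and `grad_p_us`
#'   (Pa m^-1, signed along the substrate normal).
#' @examples
#' pu <- ultrasound_pulse(p_a = 160e3)
#' ev <- evaluate_pulse(pu, medium(), seq(0, 2e-6, by = 1e-8))
#' max(abs(ev$grad_p_us))
#' @export
evaluate_pulse <- function(pulse, med, t) {
  data.frame(t = t,
             p_d = pulse_pressure(pulse, t),
             grad_p_us = pulse_gradient(pulse, med, t))
}

#' Read / write a sampled pulse envelope
#'
#' CSV interchange format for hydrophone-recorded envelopes: a header
#' line and two columns, `time_s` and `amplitude` (normalized to
#' `[0, 1]`).
#'
#' @param file Path to a CSV file.
#' @return `read_envelope` returns a data frame with columns `time_s`,
#'   `amplitude`; `write_envelope` returns `file` invisibly.
#' @export
read_envelope <- function(file) {
  env <- read.csv(file)
  if (!all(c("time_s", "amplitude") %in% names(env)))
    stop("envelope file must have columns 'time_s' and 'amplitude'")
  env[c("time_s", "amplitude")]
}

#' @rdname read_envelope
#' @param env Data frame with columns `time_s`, `amplitude`.
#' @export
write_envelope <- function(env, file) {
  ## 17 significant digits so a write/read cycle is lossless for doubles
  out <- data.frame(time_s = sprintf("%.17g", env$time_s),
                    amplitude = sprintf("%.17g", env$amplitude))
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.ultrasound_pulse <- function(x, ...) {
  cat(sprintf("ultrasound pulse: f = %g MHz, p_a = %g kPa, %d cycles (%g us)\n",
              x$f / 1e6, x$p_a / 1e3, x$n_cycles, x$duration * 1e6))
  if (is.null(x$envelope))
    cat(sprintf("  parametric envelope: linear ramp over %g cycles\n",
                x$ramp_cycles))
  else
    cat(sprintf("  sampled envelope: %d points\n", nrow(x$envelope)))
  cat(sprintf("  incidence: %g deg from substrate normal\n", x$angle_deg))
  invisible(x)
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf(
    "medium: rho_l = %g kg/m^3, mu_l = %g Pa s, c_l = %g m/s, p0 = %g kPa\n",
    x$rho_l, x$mu_l, x$c_l, x$p0 / 1e3))
  invisible(x)
}
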