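#' Synthetic-data generation settings
#'
#' Describes the observation process the generators emulate: an
#' ultrahigh-speed camera recording at 10 million frames per second with
#' a 160 nm pixel, so radius and position tracks carry +/- half-pixel
#' (80 nm) quantization noise. Every generator is a pure function of its
#' parameters and `seed`.
#'
#' @param seed Integer seed fixing all generator output.
#' @param frame_rate Sampling rate of tracks (s^-1).
#' @param pixel Pixel size (m); quantization noise is uniform on
#'   +/- half a pixel.
#' @param duration Track duration (s); NULL uses the pulse window of the
#'   generating simulation.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, frame_rate = 1e7, pixel = 160e-9,
                           duration = NULL) {
  structure(list(seed = as.integer(seed), frame_rate = frame_rate,
                 pixel = pixel, duration = duration),
            class = "synthetic_spec")
}

## evaluate fn() under a local RNG state seeded with `seed`
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Generate a noisy radius/position track
#'
#' Forward-simulates the coated-bubble radial dynamics, samples radius
#' (and, optionally, the centroid position from a translational solve)
#' at the camera frame rate, and adds uniform half-pixel quantization
#' noise, emulating feature-extracted high-speed video tracks.
#'
#' @param pulse,bubble,shell,med Model objects for the forward
#'   simulation.
#' @param spec A [synthetic_spec()].
#' @param cell Optional [cell_layer()]; when given the track includes
#'   the centroid position `x_m` from the coupled translational solve.
#' @param noise Noise half-width (m); defaults to half the pixel size,
#'   0 for noiseless tracks.
#' @param ... Passed to [solve_radial()].
#' @return List with `clean` (the [solve_radial()] result), `track`
#'   (data frame `t_s`, `R_m` and optionally `x_m`) and the `spec`.
#' @export
gen_radius_track <- function(pulse, bubble, shell, med,
                             spec = synthetic_spec(), cell = NULL,
                             noise = spec$pixel / 2, ...) {
  sol <- solve_radial(pulse, bubble, shell, med, ...)
  t_max <- if (is.null(spec$duration)) pulse$duration else spec$duration
  tt <- seq(0, min(t_max, max(sol$t)), by = 1 / spec$frame_rate)
  R_s <- approx(sol$t, sol$R, tt)$y
  track <- data.frame(t_s = tt, R_m = R_s)
  trans <- NULL
  if (!is.null(cell)) {
    trans <- solve_translation(sol, pulse, med, cell)
    track <- track[track$t_s <= max(trans$t), ]
    track$x_m <- approx(trans$t, trans$x, track$t_s, rule = 2)$y
  }
  if (noise > 0) {
    track <- with_seed(spec$seed, function() {
      track$R_m <- track$R_m + runif(nrow(track), -noise, noise)
      if (!is.null(track$x_m))
        track$x_m <- track$x_m + runif(nrow(track), -noise, noise)
      track
    })
  }
  list(clean = sol, translation = trans, track = track, spec = spec)
}

#' Generate a jetting-event dataset
#'
#' Draws equilibrium radii uniformly from `R0_range`, crosses them with
#' a pressure-amplitude grid, forward-simulates each condition and
#' tabulates the expansion metrics and jetting/cavitation labels --
#' emulating the structure of an experimental sonoporation-outcome
#' sweep.
#'
#' @param n_events Number of radius draws (>= 1).
#' @param p_a_grid Pressure amplitudes (Pa).
#' @param spec A [synthetic_spec()]; `spec$seed` fixes the radii.
#' @param R0_range Radius range (m) sampled uniformly.
#' @param shell,med Model objects shared by all events.
#' @param pulse_template Pulse whose amplitude is swept.
#' @param jet_threshold,ic_factor Passed to [classify_event()].
#' @param ... Passed to [solve_radial()].
#' @return Data frame with one row per (event, amplitude):
#'   `event`, `R0_m`, `p_a_pa`, `max_expansion_m`, `accel_proxy`,
#'   `jetting`, `sonoporation_predicted`, `inertial_cavitation`.
#' @export
gen_event_dataset <- function(n_events, p_a_grid,
                              spec = synthetic_spec(),
                              R0_range = c(1e-6, 4e-6),
                              shell = shell_params(), med = medium(),
                              pulse_template = ultrasound_pulse(p_a = 0),
                              jet_threshold = 1e-6, ic_factor = 2, ...) {
  if (n_events < 1) stop("n_events must be at least 1")
  R0s <- with_seed(spec$seed, function()
    runif(n_events, R0_range[1], R0_range[2]))
  rows <- list()
  for (ev in seq_len(n_events)) {
    bub <- bubble_params(R0 = R0s[ev])
    for (pa in p_a_grid) {
      pu <- pulse_template
      pu$p_a <- pa
      sol <- solve_radial(pu, bub, shell, med, ...)
      em <- expansion_metrics(sol, bub, pu)
      cls <- classify_event(em$max_expansion, bub$R0, jet_threshold,
                            ic_factor)
      rows[[length(rows) + 1]] <- data.frame(
        event = ev, R0_m = bub$R0, p_a_pa = pa,
        max_expansion_m = em$max_expansion,
        accel_proxy = em$accel_proxy,
        jetting = cls$jetting,
        sonoporation_predicted = cls$sonoporation_predicted,
        inertial_cavitation = cls$inertial_cavitation)
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic AFM force curves
#'
#' Hertzian approach curves over a sample/location/grid-point hierarchy
#' with a constant force baseline, contact-point jitter and
#' multiplicative force noise, emulating colloidal-probe nanoindentation
#' of a soft hydrogel.
#'
#' @param E_true True modulus (Pa).
#' @param noise_frac Multiplicative force-noise fraction (e.g. 0.05);
#'   an additive floor of 1e-11 N emulates detector noise before
#'   contact.
#' @param n_samples,n_locations,n_points Hierarchy sizes (samples x
#'   locations x grid points).
#' @param seed Integer seed.
#' @param Rbead,theta Probe parameters.
#' @param z_range Displacement span (m) of each curve.
#' @param n_z Samples per curve.
#' @param contact_frac Nominal contact point as a fraction of the span
#'   (jittered by +/- 5%).
#' @param baseline_N Baseline force offset scale (N).
#' @return List of [force_curve()] objects with labels set.
#' @export
gen_afm_curves <- function(E_true = 530, noise_frac = 0.05,
                           n_samples = 3, n_locations = 5,
                           n_points = 25, seed = 1L, Rbead = 5e-6,
                           theta = 0.5, z_range = 4e-6, n_z = 200,
                           contact_frac = 0.35, baseline_N = 5e-11) {
  if (E_true <= 0) stop("E_true must be positive")
  with_seed(seed, function() {
    curves <- list()
    for (s in seq_len(n_samples)) for (l in seq_len(n_locations))
      for (p in seq_len(n_points)) {
        z <- seq(0, z_range, length.out = n_z)
        zc <- z_range * (contact_frac + runif(1, -0.05, 0.05))
        b0 <- baseline_N * runif(1, -1, 1)
        Fm <- b0 + hertz_force(z - zc, E_true, theta, Rbead)
        if (noise_frac > 0)
          Fm <- Fm * (1 + rnorm(n_z, 0, noise_frac)) +
            rnorm(n_z, 0, 1e-11)
        curves[[length(curves) + 1]] <-
          force_curve(z, Fm, Rbead = Rbead, theta = theta,
                      location_id = sprintf("L%d", l),
                      sample_id = sprintf("S%d", s))
      }
    curves
  })
}

#' Generate a sampled pulse-envelope table
#'
#' Writes (or returns) a parametric ramp envelope sampled densely enough
#' to round-trip through [ultrasound_pulse()] without loss: at least 50
#' points per carrier cycle.
#'
#' @param f,n_cycles,ramp_cycles Pulse parameters.
#' @param points_per_cycle Samples per carrier cycle (>= 50).
#' @param file Optional path; when given the table is written with
#'   [write_envelope()].
#' @return Data frame `time_s`, `amplitude` (invisibly when written).
#' @export
gen_pulse_envelope <- function(f = 1e6, n_cycles = 20, ramp_cycles = 5,
                               points_per_cycle = 50, file = NULL) {
  if (points_per_cycle < 50)
    stop("points_per_cycle must be at least 50")
  tt <- seq(0, n_cycles / f, by = 1 / (points_per_cycle * f))
  amp <- if (ramp_cycles == 0) rep(1, length(tt))
         else pmin(tt * f / ramp_cycles, 1)
  amp[1] <- 0  # the envelope starts at zero even for a rectangular pulse
  env <- data.frame(time_s = tt, amplitude = amp)
  if (!is.null(file)) {
    write_envelope(env, file)
    return(invisible(env))
  }
  env
}
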