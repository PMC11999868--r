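#' Hertz contact force of a spherical indenter
#'
#' `F = (4/3) E/(1 - theta^2) sqrt(Rbead) iota^(3/2)` for a sphere of
#' radius `Rbead` indenting an elastic half-space by `iota`. Negative
#' indentations (pre-contact) return zero force.
#'
#' @param iota Indentation (m), vectorized.
#' @param E Apparent elastic modulus (Pa).
#' @param theta Poisson ratio (unitless), default 0.5 (incompressible).
#' @param Rbead Indenter (bead) radius (m).
#' @return Force (N).
#' @examples
#' hertz_force(1e-6, E = 530, Rbead = 5e-6) # ~2.11 nN
#' @export
hertz_force <- function(iota, E, theta = 0.5, Rbead) {
  f <- (4 / 3) * E / (1 - theta^2) * sqrt(Rbead) * pmax(iota, 0)^1.5
  f
}

#' AFM force curve
#'
#' Approach segment of a force-indentation measurement, with the probe
#' metadata needed for Hertz fitting.
#'
#' @param displacement Probe displacement (m), strictly monotone
#'   increasing along the approach.
#' @param force Measured force (N).
#' @param Rbead Bead radius (m); default 5 um (10-um-diameter colloidal
#'   probe).
#' @param theta Poisson ratio; default 0.5.
#' @param location_id,sample_id Optional grouping labels for
#'   [aggregate_modulus()].
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(displacement, force, Rbead = 5e-6, theta = 0.5,
                        location_id = NA, sample_id = NA) {
  if (length(displacement) != length(force))
    stop("displacement and force must have equal length")
  if (any(diff(displacement) <= 0))
    stop("displacement must be strictly increasing on the approach
segment")
  structure(list(displacement = displacement, force = force,
                 Rbead = Rbead, theta = theta,
                 location_id = location_id, sample_id = sample_id),
            class = "force_curve")
}

#' Fit the Hertz model to a force curve
#'
#' Joint least-squares fit of the apparent modulus `E`, the contact
#' point and (optionally) a constant force baseline. For a candidate
#' contact point the model is linear in `(baseline, E)`, so the fit
#' profiles the contact point with an inner linear solve and an outer
#' 1-D golden-section search. Curves without a clear contact point --
#' fewer than `min_post` post-contact samples, a non-positive fitted
#' modulus, or a fitted indentation signal that does not rise above the
#' residual noise -- are flagged invalid.
#'
#' @param curve A [force_curve()].
#' @param theta Poisson ratio override; defaults to the curve's.
#' @param Rbead Bead radius override; defaults to the curve's.
#' @param baseline Fit a constant force offset (default TRUE).
#' @param min_post Minimum number of post-contact samples (default 10).
#' @param snr_min Minimum ratio of fitted indentation force span to
#'   residual RMS for a "clear" contact point.
#' @return An object of class `hertz_fit`: list with `E` (Pa),
#'   `contact_point` (m), `baseline` (N), `residual_rms` (N), `valid`
#'   and the grouping labels of the curve.
#' @export
fit_modulus <- function(curve, theta = curve$theta, Rbead = curve$Rbead,
                        baseline = TRUE, min_post = 10, snr_min = 5) {
  z <- curve$displacement
  Fo <- curve$force
  n <- length(z)
  pre <- (4 / 3) / (1 - theta^2) * sqrt(Rbead)
  fit_at <- function(zc) {
    w <- pre * pmax(z - zc, 0)^1.5
    npost <- sum(z > zc)
    if (npost < 3) return(list(ssr = Inf))
    if (baseline) {
      fit <- lm(Fo ~ w)
      b0 <- coef(fit)[[1]]; E <- coef(fit)[[2]]
      r <- Fo - (b0 + E * w)
    } else {
      E <- sum(w * Fo) / sum(w * w)
      b0 <- 0
      r <- Fo - E * w
    }
    list(ssr = sum(r^2), E = E, baseline = b0, w = w, npost = npost)
  }
  ## the contact point floats freely (down to 3 post-contact samples);
  ## the min_post discard rule is applied to the best fit afterwards
  lo <- z[1]
  hi <- z[n - 3]
  if (hi <= lo) {
    return(structure(list(E = NA_real_, contact_point = NA_real_,
                          baseline = NA_real_, residual_rms = NA_real_,
                          valid = FALSE, location_id = curve$location_id,
                          sample_id = curve$sample_id),
                     class = "hertz_fit"))
  }
  ## coarse scan guards against local minima of the profiled SSR, then a
  ## golden-section refinement around the best bracket
  grid <- seq(lo, hi, length.out = 60)
  ssr_grid <- vapply(grid, function(zc) fit_at(zc)$ssr, numeric(1))
  i0 <- which.min(ssr_grid)
  bl <- grid[max(i0 - 1, 1)]
  bu <- grid[min(i0 + 1, length(grid))]
  opt <- optimize(function(zc) fit_at(zc)$ssr, c(bl, bu),
                  tol = (hi - lo) * 1e-7)
  if (fit_at(opt$minimum)$ssr > ssr_grid[i0]) opt$minimum <- grid[i0]
  best <- fit_at(opt$minimum)
  rms <- sqrt(best$ssr / n)
  span <- if (is.finite(best$ssr)) max(best$E * best$w) - min(best$E * best$w) else 0
  valid <- is.finite(best$ssr) && !is.na(best$E) && best$E > 0 &&
    best$npost >= min_post && (rms == 0 || span / rms >= snr_min)
  structure(list(E = if (valid) best$E else NA_real_,
                 contact_point = opt$minimum,
                 baseline = best$baseline,
                 residual_rms = rms, valid = valid,
                 location_id = curve$location_id,
                 sample_id = curve$sample_id),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("Hertz fit: E = %.4g Pa, contact at %.4g um, rms %.3g N\n",
                x$E, x$contact_point * 1e6, x$residual_rms))
  else
    cat("Hertz fit: invalid (no clear contact point)\n")
  invisible(x)
}

#' Aggregate apparent moduli over a measurement hierarchy
#'
#' Follows the grid-location-sample aggregation used for hydrogel
#' characterization: the median modulus over the grid points of each
#' location, the mean of those medians over the locations of each
#' sample, and the mean and standard deviation of the sample values.
#' Invalid fits and empty groups are dropped (with a warning).
#'
#' @param fits Either a list of [fit_modulus()] results or a data frame
#'   with columns `E`, `valid`, `location_id`, `sample_id`.
#' @return List with `E_mean` (Pa), `E_sd` (Pa), `n_samples`,
#'   `per_sample` and `per_location` data frames.
#' @export
aggregate_modulus <- function(fits) {
  if (!is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(E = f$E, valid = f$valid,
                 location_id = f$location_id, sample_id = f$sample_id)))
  }
  ok <- fits$valid & !is.na(fits$E)
  if (any(!ok)) warning(sprintf("%d invalid fit(s) excluded",
                                sum(!ok)))
  fits <- fits[ok, ]
  if (nrow(fits) == 0) stop("no valid fits to aggregate")
  key <- interaction(fits$sample_id, fits$location_id, drop = TRUE)
  per_loc <- do.call(rbind, lapply(split(fits, key), function(g)
    data.frame(sample_id = g$sample_id[1], location_id = g$location_id[1],
               E_median = median(g$E), n = nrow(g))))
  per_sample <- do.call(rbind, lapply(split(per_loc, per_loc$sample_id),
    function(g) data.frame(sample_id = g$sample_id[1],
                           E_mean = mean(g$E_median),
                           n_locations = nrow(g))))
  list(E_mean = mean(per_sample$E_mean),
       E_sd = if (nrow(per_sample) > 1) sd(per_sample$E_mean) else 0,
       n_samples = nrow(per_sample),
       per_sample = per_sample, per_location = per_loc)
}

#' Read / write AFM force curves
#'
#' CSV format: columns `z_m` (displacement, m), `F_N` (force, N) and
#' optional `location_id`, `sample_id` group labels; one file may hold
#' several curves distinguished by the label pair plus a `curve_id`
#' column.
#'
#' @param file CSV path.
#' @param Rbead,theta Probe metadata applied to all curves.
#' @return List of [force_curve()] objects.
#' @export
read_force_curves <- function(file, Rbead = 5e-6, theta = 0.5) {
  df <- read.csv(file)
  if (!all(c("z_m", "F_N") %in% names(df)))
    stop("force-curve file must have columns 'z_m' and 'F_N'")
  if (!"curve_id" %in% names(df)) df$curve_id <- 1
  lapply(split(df, df$curve_id), function(g)
    force_curve(g$z_m, g$F_N, Rbead = Rbead, theta = theta,
                location_id = if ("location_id" %in% names(g))
                  g$location_id[1] else NA,
                sample_id = if ("sample_id" %in% names(g))
                  g$sample_id[1] else NA))
}
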