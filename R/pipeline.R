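#' Default run configuration
#'
#' Nested configuration describing the reference study conditions: a
#' 3-um lipid-coated bubble on a 12-um endothelial cell layer over a
#' rigid plastic substrate, driven by a 20-cycle 1-MHz ramped pulse at a
#' low (60 kPa) and a high (160 kPa) amplitude.
#'
#' @return Nested list with sections `medium`, `bubble`, `shell`,
#'   `cell`, `pulse`, `jet`, `thresholds`, `synthetic` and `seed`.
#' @export
default_config <- function() {
  list(
    medium = list(rho_l = 998, mu_l = 1e-3, c_l = 1482, p0 = 101325,
                  p_v = 2645, sigma_w = 0.072, T_l = 22),
    bubble = list(R0_m = 3e-6, gas_model = "polytropic", kappa = 1.07,
                  rho_g = 10),
    shell = list(chi = 0.5, kappa_s = 7e-9, sigma_R0 = 0.02),
    cell = list(L_m = 12e-6, beta = 0.8, c_beta = 1),
    pulse = list(f_hz = 1e6, n_cycles = 20, ramp_cycles = 5,
                 angle_deg = 15, envelope_file = NULL,
                 p_a_low_pa = 60e3, p_a_high_pa = 160e3),
    jet = list(u_jet = 60, R_jet_m = 0.75e-6, u_stream = 0.1),
    thresholds = list(jet_threshold_m = 1e-6, ic_factor = 2),
    synthetic = list(frame_rate = 1e7, pixel_m = 160e-9),
    solver = list(samples_per_cycle = 200, rtol = 1e-8),
    seed = 1L
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration, fills missing entries from
#' [default_config()] and validates units and ranges before any run.
#'
#' @param file YAML path; NULL returns the validated defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(file = NULL) {
  cfg <- default_config()
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    for (sec in names(user)) {
      if (is.list(user[[sec]]) && sec %in% names(cfg))
        cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
      else cfg[[sec]] <- user[[sec]]
    }
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg Configuration list.
#' @export
validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(medium$rho_l > 0, medium$mu_l > 0, medium$c_l > 0,
              medium$p0 > medium$p_v,
              bubble$R0_m > 0, shell$chi > 0, shell$kappa_s >= 0,
              shell$sigma_R0 >= 0, shell$sigma_R0 <= medium$sigma_w,
              cell$L_m > 0, cell$beta > 0, cell$beta < 1,
              cell$c_beta > 0,
              pulse$f_hz > 0, pulse$n_cycles >= 1,
              pulse$ramp_cycles >= 0,
              pulse$p_a_low_pa >= 0, pulse$p_a_high_pa >= 0,
              jet$u_jet >= 0, jet$R_jet_m >= 0, jet$u_stream >= 0,
              thresholds$jet_threshold_m > 0, thresholds$ic_factor > 0)
  })
  cfg
}

## materialize model objects from a config section set
config_objects <- function(cfg, p_a) {
  med <- medium(cfg$medium$rho_l, cfg$medium$mu_l, cfg$medium$c_l,
                cfg$medium$p0, cfg$medium$p_v, cfg$medium$sigma_w,
                cfg$medium$T_l)
  env <- if (!is.null(cfg$pulse$envelope_file))
    read_envelope(cfg$pulse$envelope_file) else NULL
  pulse <- ultrasound_pulse(cfg$pulse$f_hz, p_a, cfg$pulse$n_cycles,
                            cfg$pulse$ramp_cycles, cfg$pulse$angle_deg,
                            envelope = env)
  list(med = med, pulse = pulse,
       bubble = bubble_params(cfg$bubble$R0_m, cfg$bubble$gas_model,
                              kappa = cfg$bubble$kappa,
                              rho_g = cfg$bubble$rho_g),
       shell = shell_params(cfg$shell$chi, cfg$shell$kappa_s,
                            cfg$shell$sigma_R0),
       cell = cell_layer(cfg$cell$L_m, cfg$cell$beta, cfg$cell$c_beta),
       jet = jet_params(cfg$jet$u_jet, cfg$jet$R_jet_m))
}

## run radial + translation + impulse for one amplitude
run_single_case <- function(cfg, p_a) {
  ob <- config_objects(cfg, p_a)
  radial <- solve_radial(ob$pulse, ob$bubble, ob$shell, ob$med,
                         samples_per_cycle = cfg$solver$samples_per_cycle,
                         rtol = cfg$solver$rtol)
  translation <- solve_translation(radial, ob$pulse, ob$med, ob$cell)
  impulses <- if (p_a > 0)
    cycle_impulses(radial, translation, ob$pulse, ob$med, ob$cell)
  else NULL
  em <- expansion_metrics(radial, ob$bubble, ob$pulse)
  list(objects = ob, radial = radial, translation = translation,
       impulses = impulses, metrics = em,
       labels = classify_event(em$max_expansion, ob$bubble$R0,
                               cfg$thresholds$jet_threshold_m,
                               cfg$thresholds$ic_factor))
}

#' Case study: low- and high-amplitude bubble-cell interaction
#'
#' Runs the coupled radial + translational model at the configured low
#' and high pressure amplitudes and reports radius/position solutions,
#' per-cycle Kelvin-impulse decompositions and expansion metrics, with a
#' summary of the substrate-to-ultrasound impulse ratios.
#'
#' @param cfg Configuration from [read_config()] / [default_config()].
#' @param out Optional output directory; when given, CSV tables and a
#'   JSON manifest are written there.
#' @return List with `low` and `high` case results (each as returned by
#'   the internal single-case runner) and `summary`.
#' @export
run_case_study <- function(cfg = default_config(), out = NULL) {
  low <- run_single_case(cfg, cfg$pulse$p_a_low_pa)
  high <- run_single_case(cfg, cfg$pulse$p_a_high_pa)
  summ <- list(
    low = list(p_a = cfg$pulse$p_a_low_pa,
               max_expansion_m = low$metrics$max_expansion,
               x_max_m = max(low$translation$x),
               contact = low$translation$contact$occurred,
               min_ratio_sub_us = if (!is.null(low$impulses))
                 min(low$impulses$ratio_sub_us) else NA),
    high = list(p_a = cfg$pulse$p_a_high_pa,
                max_expansion_m = high$metrics$max_expansion,
                x_max_m = max(high$translation$x),
                contact = high$translation$contact$occurred,
                min_ratio_sub_us = if (!is.null(high$impulses))
                  min(high$impulses$ratio_sub_us) else NA))
  res <- list(low = low, high = high, summary = summ)
  if (!is.null(out)) write_case_study(res, cfg, out)
  res
}

write_case_study <- function(res, cfg, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("low", "high")) {
    cs <- res[[nm]]
    write.csv(data.frame(t_s = cs$radial$t, R_m = cs$radial$R,
                         Rdot = cs$radial$Rdot, V_m3 = cs$radial$V),
              file.path(out, paste0("radial_", nm, ".csv")),
              row.names = FALSE)
    write.csv(data.frame(t_s = cs$translation$t, x_m = cs$translation$x,
                         eps = cs$translation$eps),
              file.path(out, paste0("translation_", nm, ".csv")),
              row.names = FALSE)
    if (!is.null(cs$impulses))
      write.csv(cs$impulses,
                file.path(out, paste0("impulses_", nm, ".csv")),
                row.names = FALSE)
  }
  manifest <- list(config = cfg, summary = res$summary,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}

#' Minimum jetting pressure for one bubble size
#'
#' Bisects the pressure amplitude until the maximum radial expansion
#' crosses the jetting threshold.
#'
#' @param R0 Equilibrium radius (m).
#' @param cfg Configuration (pulse/shell/medium template).
#' @param p_bounds Bisection bounds on the amplitude (Pa).
#' @param tol_pa Bisection tolerance (Pa).
#' @return List with `p_threshold_pa` (NA when not reached within
#'   bounds) and `reached`.
#' @export
jetting_threshold <- function(R0, cfg = default_config(),
                              p_bounds = c(5e3, 400e3), tol_pa = 1e3) {
  thr <- cfg$thresholds$jet_threshold_m
  expansion_at <- function(p_a) {
    ob <- config_objects(cfg, p_a)
    ob$bubble <- bubble_params(R0, cfg$bubble$gas_model,
                               kappa = cfg$bubble$kappa,
                               rho_g = cfg$bubble$rho_g)
    sol <- solve_radial(ob$pulse, ob$bubble, ob$shell, ob$med,
                        samples_per_cycle = cfg$solver$samples_per_cycle,
                        rtol = cfg$solver$rtol)
    max(sol$R) - R0
  }
  lo <- p_bounds[1]; hi <- p_bounds[2]
  if (expansion_at(hi) < thr)
    return(list(p_threshold_pa = NA_real_, reached = FALSE))
  if (expansion_at(lo) >= thr)
    return(list(p_threshold_pa = lo, reached = TRUE))
  while (hi - lo > tol_pa) {
    mid <- 0.5 * (lo + hi)
    if (expansion_at(mid) >= thr) hi <- mid else lo <- mid
  }
  list(p_threshold_pa = 0.5 * (lo + hi), reached = TRUE)
}

#' Jetting-threshold map over bubble size
#'
#' For each equilibrium radius on a grid, bisects the pressure
#' amplitude at which the maximum radial expansion reaches the jetting
#' threshold; the minimum of the resulting curve marks the resonant
#' radius.
#'
#' @param cfg Configuration.
#' @param R0_grid Radii (m).
#' @param p_bounds,tol_pa Passed to [jetting_threshold()].
#' @param out Optional output directory for a CSV of the map.
#' @return Data frame `R0_m`, `p_threshold_pa`, `reached`, with
#'   attributes `min_threshold_pa` and `resonant_R0_m`.
#' @export
run_threshold_map <- function(cfg = default_config(),
                              R0_grid = seq(1e-6, 4e-6, by = 0.25e-6),
                              p_bounds = c(5e3, 400e3), tol_pa = 1e3,
                              out = NULL) {
  rows <- lapply(R0_grid, function(R0) {
    th <- jetting_threshold(R0, cfg, p_bounds, tol_pa)
    data.frame(R0_m = R0, p_threshold_pa = th$p_threshold_pa,
               reached = th$reached)
  })
  map <- do.call(rbind, rows)
  ok <- map$reached
  i_min <- which.min(ifelse(ok, map$p_threshold_pa, Inf))
  attr(map, "min_threshold_pa") <- map$p_threshold_pa[i_min]
  attr(map, "resonant_R0_m") <- map$R0_m[i_min]
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.csv(map, file.path(out, "threshold_map.csv"),
              row.names = FALSE)
  }
  map
}

#' Stress-mechanism comparison for the high-amplitude case
#'
#' Simulates the configured high-amplitude case with the coupled model
#' and assembles the stress comparison across mechanisms (see
#' [stress_report()]).
#'
#' @param cfg Configuration.
#' @param out Optional output directory (series CSV + peak-table JSON).
#' @return The [stress_report()] of the high-amplitude case.
#' @export
run_stress_comparison <- function(cfg = default_config(), out = NULL) {
  case <- run_single_case(cfg, cfg$pulse$p_a_high_pa)
  rep <- stress_report(case$radial, case$translation,
                       case$objects$pulse, case$objects$med,
                       case$objects$jet,
                       u_stream = cfg$jet$u_stream,
                       sample_rate = cfg$synthetic$frame_rate,
                       jet_threshold = cfg$thresholds$jet_threshold_m,
                       cell = case$objects$cell)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.csv(rep$series, file.path(out, "stress_series.csv"),
              row.names = FALSE)
    jsonlite::write_json(rep$peaks, file.path(out, "stress_peaks.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  rep
}
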