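## Run configuration (YAML/JSON), synthetic target-curve fixtures, and
## result writing.  Units: lengths um, stresses kPa, forces kPa um^2.

#' Default run configuration
#'
#' Nested list with every tunable of the pipeline, defaulting to the
#' standard white-matter study conditions: 0.4 x 10 x 5.68 um box, 0.4 um
#' axon diameter, 53% volume fraction, coupling threshold 1.08 with
#' 8/20/44% fractions at stretches 1.06/1.12/1.25, alpha 8.22, axon three
#' times stiffer than matrix, bracket (20, 50) kPa, tolerance 1.0 kPa and
#' 20 sample points.
#'
#' @return Named nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(size_x = 0.4, size_y = 10, size_z = 5.68, radius = 0.2,
                    target_volume_fraction = 0.53, vf_tolerance = 0.01,
                    packing_bound = 0.9,
                    tortuosity = list(mean = 1.13, sd = 0.06,
                                      min = 1.02, max = 1.30),
                    n_waypoints = 8L, n_subsegments = 50L,
                    end_offset_sd = 0.5),
    kinematics = list(threshold_undulation = 1.08,
                      stage_breaks = c(1.06, 1.12, 1.25),
                      stage_fractions = c(0.08, 0.20, 0.44),
                      policy = "straightest"),
    material = list(mu_axon_kPa = 32.8, mu_ratio_axon_to_ecm = 3,
                    alpha = 8.22, bulk_penalty_factor = 100),
    load = list(stages = c(1.06, 1.12, 1.25), substeps = 6L),
    mesh = list(element_size = 0.2, k_high_factor = 1e3,
                k_low_factor = 1e-3),
    inverse = list(mu_min_kPa = 20, mu_max_kPa = 50, tol_kPa = 1.0,
                   n_sample_points = 20L),
    seed = 1L), class = "run_config")
}

merge_validate <- function(defaults, user, path = "") {
  if (!is.list(user)) stop(sprintf("schema error: '%s' must be a mapping",
                                   path))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("schema error: unknown configuration key(s): %s",
                 paste0(path, unknown, collapse = ", ")))
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      out[[nm]] <- merge_validate(defaults[[nm]], as.list(user[[nm]]),
                                  paste0(path, nm, "/"))
    else out[[nm]] <- user[[nm]]
  }
  out
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  if (g$target_volume_fraction < 0)
    stop("schema error: geometry/target_volume_fraction must be >= 0")
  if (g$radius < 0) stop("schema error: geometry/radius must be >= 0")
  if (any(c(g$size_x, g$size_y, g$size_z) <= 0))
    stop("schema error: geometry sizes must be > 0")
  if (cfg$material$mu_axon_kPa <= 0)
    stop("schema error: material/mu_axon_kPa must be > 0")
  if (cfg$inverse$mu_min_kPa > cfg$inverse$mu_max_kPa)
    stop("schema error: inverse bracket must satisfy mu_min <= mu_max")
  if (any(diff(cfg$load$stages) <= 0) || any(cfg$load$stages <= 1))
    stop("schema error: load/stages must be strictly increasing and > 1")
  cfg
}

#' Read and validate a run configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON; unknown keys are rejected and missing
#' keys are filled with the defaults of [default_config()].  An empty file
#' yields the full default configuration.
#'
#' @param path configuration file, or `NULL` for pure defaults.
#' @return Validated `run_config`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(validate_config(default_config()))
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(user)) user <- list()
  cfg <- merge_validate(unclass(default_config()), user)
  validate_config(structure(cfg, class = "run_config"))
}

## Builders from a validated config ---------------------------------------

config_rve <- function(cfg) {
  g <- cfg$geometry
  rve_config(domain = box_domain(g$size_x, g$size_y, g$size_z),
             radius = g$radius,
             target_volume_fraction = g$target_volume_fraction,
             vf_tolerance = g$vf_tolerance, packing_bound = g$packing_bound,
             tortuosity = g$tortuosity, n_waypoints = g$n_waypoints,
             n_subsegments = g$n_subsegments,
             end_offset_sd = g$end_offset_sd)
}

config_rule <- function(cfg)
  coupling_rule(cfg$kinematics$threshold_undulation,
                cfg$kinematics$stage_breaks, cfg$kinematics$stage_fractions)

config_materials <- function(cfg, mu_axon = NULL) {
  m <- cfg$material
  wm_materials(if (is.null(mu_axon)) m$mu_axon_kPa else mu_axon,
               alpha = m$alpha, mu_ratio = m$mu_ratio_axon_to_ecm,
               bulk_factor = m$bulk_penalty_factor)
}

config_program <- function(cfg)
  load_program(cfg$load$stages, cfg$load$substeps)

#' Synthetic uniaxial Ogden target curve
#'
#' Stand-in for an untabulated experimental tension curve: nominal stress
#' of the incompressible uniaxial Ogden law at `n_points + 1` stretches
#' including the zero-stress point at `lambda = 1`, tagged `"synthetic"`.
#'
#' @param mu_fit fitted shear modulus in kPa (default 32.8).
#' @param alpha fitted nonlinearity (default 8.22).
#' @param lambda_max final stretch (default 1.25).
#' @param n_points number of intervals (default 50).
#' @return A [stress_stretch_curve()].
#' @export
synth_target_curve <- function(mu_fit = 32.8, alpha = 8.22,
                               lambda_max = 1.25, n_points = 50L) {
  stopifnot(mu_fit > 0, lambda_max > 1, n_points >= 1L)
  mat <- ogden_material(mu_fit, alpha)
  lam <- seq(1, lambda_max, length.out = n_points + 1L)
  stress_stretch_curve(lam, uniaxial_nominal_stress(lam, mat), "synthetic")
}

#' Read a stress-stretch curve from CSV
#'
#' Expects columns `lambda` and a stress column (`S_kPa` or `S33_kPa`); a
#' `lambda = 1` row is optional.
#'
#' @param path CSV file.
#' @param source curve provenance tag.
#' @return A [stress_stretch_curve()].
#' @export
read_curve_csv <- function(path, source = "experimental") {
  df <- read.csv(path)
  as_curve(df, source)
}

#' Write the standard result bundle of a run
#'
#' Config echo (YAML), seed, stress-stretch curve CSV, geometry JSON, and
#' optional trace CSV / VTK fields — everything needed to reproduce the
#' run.
#'
#' @param dir output directory (created if missing).
#' @param cfg the `run_config` used.
#' @param rve the `rve_geometry`, or `NULL`.
#' @param result a `homogenized_result`, or `NULL`.
#' @param fit an [identify_shear_modulus()] result, or `NULL`.
#' @return The output directory, invisibly.
#' @export
write_results <- function(dir, cfg, rve = NULL, result = NULL, fit = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  if (!is.null(rve)) rve_to_json(rve, file.path(dir, "geometry.json"))
  if (!is.null(result)) {
    write_curve_csv(result$curve, file.path(dir, "curve.csv"))
    write.csv(tortuosity_trace(result), file.path(dir, "tortuosity.csv"),
              row.names = FALSE, quote = FALSE)
    if (!is.null(result$model))
      write_vtk_fields(result$model, result$u, file.path(dir, "fields.vtk"))
  }
  if (!is.null(fit)) {
    write.csv(fit$trace, file.path(dir, "trace.csv"), row.names = FALSE,
              quote = FALSE)
    write_curve_csv(fit$fitted_curve, file.path(dir, "fitted_curve.csv"))
  }
  invisible(dir)
}
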