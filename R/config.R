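#' Default run configuration
#'
#' Full pipeline defaults: the 350 kHz / 44 mm / 31.5 mm bowl calibrated to
#' 1 MPa focal pressure, the layered water/skin/tumor/muscle phantom
#' (0.8 mm skin, 6 mm tumor at the focus), a 0.4 mm grid, 10 min
#' equilibration, 20 min relay-controlled treatment at 42 / 41.5 deg C,
#' standard CEM43 R-values, the small-animal irradiator machine factors,
#' and the four-arm synthetic cohort at the one-week analysis day.
#' Interface units are mm / min / MPa; everything is converted to SI
#' internally.
#'
#' @return nested configuration list (see [load_config()]).
#' @export
default_config <- function() {
  list(
    transducer = list(frequency_hz = 350e3, aperture_mm = 44,
                      active_mm = 40, opening_mm = 12,
                      focal_length_mm = 31.5, focal_pressure_mpa = 1),
    phantom = list(standoff_mm = NULL, skin_mm = 0.8, tumor_diameter_mm = 6),
    materials = list(),
    grid = list(spacing_mm = 0.4, extent_mm = c(40, 40, 50)),
    bhte = list(dt_s = NULL, blood_temperature_c = 37,
                blood_specific_heat = 3700, initial_tissue_c = 37,
                initial_water_c = 23, equilibration_s = 600,
                treatment_s = 1200, boundary = "dirichlet_z",
                dose_interval_s = 1),
    controller = list(upper_c = 42, lower_c = 41.5),
    dose = list(r_above = 0.5, r_below = 0.25),
    rt = list(dose_gy = 2, rate_gy_min = 4.1, output_factor = 0.79,
              depth_mm = 3),
    analysis = list(day = 7, alpha = 0.05),
    synth = list(enabled = TRUE, preset = "four-arm-day7")
  )
}

check_unknown_keys <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(user[[key]]) && is.list(defaults[[key]]) &&
        length(defaults[[key]]) > 0 && !is.null(names(defaults[[key]])) &&
        path != "materials")
      check_unknown_keys(user[[key]], defaults[[key]], full)
  }
  invisible(TRUE)
}

validate_config <- function(cfg) {
  fail <- function(key, msg) stop("invalid configuration: ", key, " ", msg)
  tr <- cfg$transducer
  if (tr$frequency_hz <= 0) fail("transducer.frequency_hz", "must be > 0")
  if (tr$aperture_mm >= 2 * tr$focal_length_mm)
    fail("transducer.aperture_mm",
         "must be smaller than twice the focal length")
  if (tr$focal_pressure_mpa <= 0)
    fail("transducer.focal_pressure_mpa", "must be > 0")
  if (cfg$phantom$skin_mm <= 0) fail("phantom.skin_mm", "must be > 0")
  if (cfg$phantom$tumor_diameter_mm < 0)
    fail("phantom.tumor_diameter_mm", "must be >= 0")
  if (cfg$grid$spacing_mm <= 0) fail("grid.spacing_mm", "must be > 0")
  if (length(cfg$grid$extent_mm) != 3 || any(cfg$grid$extent_mm <= 0))
    fail("grid.extent_mm", "must be three positive extents")
  if (!(cfg$controller$lower_c < cfg$controller$upper_c))
    fail("controller.lower_c", "must be below controller.upper_c")
  if (cfg$bhte$equilibration_s < 0)
    fail("bhte.equilibration_s", "must be >= 0")
  if (cfg$bhte$treatment_s <= 0) fail("bhte.treatment_s", "must be > 0")
  if (cfg$dose$r_above <= 0 || cfg$dose$r_above > 1)
    fail("dose.r_above", "must be in (0, 1]")
  if (cfg$dose$r_below <= 0 || cfg$dose$r_below > 1)
    fail("dose.r_below", "must be in (0, 1]")
  if (cfg$rt$dose_gy <= 0) fail("rt.dose_gy", "must be > 0")
  if (cfg$rt$rate_gy_min <= 0) fail("rt.rate_gy_min", "must be > 0")
  if (cfg$rt$output_factor <= 0 || cfg$rt$output_factor > 1)
    fail("rt.output_factor", "must be in (0, 1]")
  for (med in names(cfg$materials)) {
    if (!med %in% material_table()$medium)
      fail(paste0("materials.", med), "is not a known medium")
    bad <- setdiff(names(cfg$materials[[med]]),
                   setdiff(names(material_table()), "medium"))
    if (length(bad))
      fail(paste0("materials.", med, ".", bad[1]),
           "is not a known material property")
  }
  invisible(cfg)
}

merge_config <- function(defaults, user) {
  for (key in names(user)) {
    if (is.list(user[[key]]) && is.list(defaults[[key]]) &&
        key != "materials") {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]])
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, overlays it on [default_config()], rejects
#' unknown keys and checks the module invariants; validation errors name
#' the offending key.  An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path, or `NULL`/a list for programmatic use.
#' @return validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else if (is.list(path)) path
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  check_unknown_keys(user, defaults)
  cfg <- merge_config(defaults, user)
  validate_config(cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

config_materials <- function(cfg) {
  tab <- material_table()
  for (med in names(cfg$materials)) {
    i <- match(med, tab$medium)
    for (prop in names(cfg$materials[[med]]))
      tab[i, prop] <- cfg$materials[[med]][[prop]]
  }
  tab
}

config_objects <- function(cfg) {
  tr <- transducer_spec(frequency = cfg$transducer$frequency_hz,
                        aperture_diameter = cfg$transducer$aperture_mm * 1e-3,
                        active_diameter = cfg$transducer$active_mm * 1e-3,
                        central_opening = cfg$transducer$opening_mm * 1e-3,
                        radius_of_curvature =
                          cfg$transducer$focal_length_mm * 1e-3)
  grid <- simulation_grid(spacing = cfg$grid$spacing_mm * 1e-3,
                          extent = cfg$grid$extent_mm * 1e-3)
  phantom <- layered_phantom(
    focal_length = cfg$transducer$focal_length_mm * 1e-3,
    skin_thickness = cfg$phantom$skin_mm * 1e-3,
    tumor_diameter = cfg$phantom$tumor_diameter_mm * 1e-3,
    water_standoff = if (is.null(cfg$phantom$standoff_mm)) NULL
      else cfg$phantom$standoff_mm * 1e-3)
  list(transducer = tr, grid = grid, phantom = phantom,
       materials = build_phantom_fixture(phantom, grid,
                                         config_materials(cfg)),
       bcfg = bhte_config(dt = cfg$bhte$dt_s,
                          blood_temperature = cfg$bhte$blood_temperature_c,
                          blood_specific_heat = cfg$bhte$blood_specific_heat,
                          initial_tissue = cfg$bhte$initial_tissue_c,
                          initial_water = cfg$bhte$initial_water_c,
                          equilibration = cfg$bhte$equilibration_s,
                          boundary = cfg$bhte$boundary,
                          dose_interval = cfg$bhte$dose_interval_s),
       controller = hysteresis_controller(upper = cfg$controller$upper_c,
                                          lower = cfg$controller$lower_c))
}

#' Run the full treatment-simulation pipeline
#'
#' Executes acoustics (source calibration, pressure field, heat source),
#' equilibration, the relay-controlled treatment, CEM43 dose accumulation,
#' radiotherapy beam-time planning and, if enabled, synthetic-cohort
#' generation plus the growth statistics, logging one line of key scalars
#' per stage.  All outputs are reproducible from `config` and `seed` alone.
#'
#' @param config a `run_config` from [load_config()] (default: full
#'   defaults).
#' @param seed integer seed for the synthetic cohort stage.
#' @param out_dir optional directory; when given, stage outputs (axial
#'   profile, sensor trace, dose summary, cohort and statistics CSVs) and a
#'   JSON manifest are written there.
#' @param verbose print per-stage log lines.
#' @return list with all stage results.
#' @export
run_pipeline <- function(config = load_config(), seed = 1, out_dir = NULL,
                         verbose = TRUE) {
  if (!inherits(config, "run_config")) config <- load_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  obj <- config_objects(config)

  tr <- calibrate_transducer(obj$transducer,
                             config$transducer$focal_pressure_mpa * 1e6)
  field <- rayleigh_pressure_field(tr, obj$grid, obj$materials)
  metrics <- focal_metrics(field)
  ispta <- intensity_from_pressure(config$transducer$focal_pressure_mpa * 1e6)
  say("acoustics: focal peak %.3g MPa, -3dB %.2f x %.2f mm, Ispta %.1f W/cm^2",
      metrics$peak_pa / 1e6, metrics$lateral_width * 1e3,
      metrics$axial_length * 1e3, ispta * 1e-4)
  Q <- heat_source(field, obj$materials)

  T0 <- equilibrate(obj$materials, obj$bcfg)
  say("equilibration: %.0f s, tumor-center %.2f C", T0$time,
      T0$temperature[tumor_center_index(obj$materials)[1],
                     tumor_center_index(obj$materials)[2],
                     tumor_center_index(obj$materials)[3]])

  hist <- run_treatment(T0, Q, obj$controller, config$bhte$treatment_s,
                        obj$bcfg, obj$materials,
                        r_above = config$dose$r_above,
                        r_below = config$dose$r_below)
  t42 <- time_to_temperature(hist, obj$controller$upper)
  say("treatment: reached %.1f C at %.0f s; duty %.0f%%",
      obj$controller$upper, if (is.na(t42)) NA_real_ else t42 - T0$time,
      100 * mean(hist$trace$source_on))

  dsum <- dose_summary(hist$dose, obj$grid)
  say("dose: max CEM43 %.2f, mean %.3f", dsum$max_cem43, dsum$mean_cem43)

  plan <- rt_plan(config$rt$dose_gy, config$rt$rate_gy_min,
                  config$rt$output_factor, config$rt$depth_mm)
  say("rt: %.3g Gy -> %.3f min beam-on", plan$dose_gy, plan$beam_on_min)

  cohort <- NULL
  growth <- NULL
  if (isTRUE(config$synth$enabled)) {
    preset <- cohort_preset(config$synth$preset)
    cohort <- generate_cohort(preset$specs, preset$days, seed = seed)
    growth <- analyze_growth(cohort, day = preset$days[length(preset$days)],
                             alpha = config$analysis$alpha)
    say("growth: ANOVA p = %.3g over %d groups", growth$anova$p_value,
        nrow(growth$summaries))
  }

  result <- list(config = config, seed = seed, transducer = tr,
                 field_metrics = metrics, ispta_w_m2 = ispta,
                 heat_source = Q, equilibrated = T0, history = hist,
                 dose_summary = dsum, rt = plan, cohort = cohort,
                 growth = growth,
                 axial = axial_profile(field))
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Time at which the sensor first reaches a temperature
#'
#' @param history a `temperature_history`.
#' @param target temperature in deg C.
#' @return absolute time in s, or `NA` if never reached.
#' @export
time_to_temperature <- function(history, target = 42) {
  i <- which(history$trace$sensor_c >= target)
  if (!length(i)) return(NA_real_)
  history$trace$time_s[i[1]]
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$axial, file.path(out_dir, "axial_profile.csv"),
            row.names = FALSE)
  write.csv(result$history$trace, file.path(out_dir, "sensor_trace.csv"),
            row.names = FALSE)
  write.csv(result$dose_summary, file.path(out_dir, "dose_summary.csv"),
            row.names = FALSE)
  if (!is.null(result$cohort))
    write_caliper_csv(result$cohort, file.path(out_dir, "cohort.csv"))
  if (!is.null(result$growth)) {
    write.csv(result$growth$summaries,
              file.path(out_dir, "group_summaries.csv"), row.names = FALSE)
    if (!is.null(result$growth$welch))
      write.csv(result$growth$welch,
                file.path(out_dir, "welch_tests.csv"), row.names = FALSE)
  }
  manifest <- list(
    package = "fusht",
    version = as.character(utils::packageVersion("fusht")),
    seed = result$seed,
    config = unclass(result$config),
    key_scalars = list(
      focal_peak_mpa = result$field_metrics$peak_pa / 1e6,
      lateral_width_mm = result$field_metrics$lateral_width * 1e3,
      axial_length_mm = result$field_metrics$axial_length * 1e3,
      ispta_w_cm2 = result$ispta_w_m2 * 1e-4,
      max_cem43 = result$dose_summary$max_cem43,
      beam_on_min = result$rt$beam_on_min),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
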