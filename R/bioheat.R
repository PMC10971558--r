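#' Pennes bioheat solver configuration
#'
#' @param dt explicit time step in s; `NULL` auto-selects half the stability
#'   bound of the grid/materials at hand.
#' @param blood_temperature arterial temperature T_a in deg C.
#' @param blood_specific_heat blood specific heat C_b in J/(kg*C).
#' @param initial_tissue initial tissue temperature in deg C.
#' @param initial_water initial water temperature in deg C.
#' @param equilibration source-free equilibration duration in s.
#' @param boundary `"dirichlet_z"` holds the water voxels of the two grid
#'   faces perpendicular to the propagation axis at their initial
#'   temperatures; every other boundary (including tissue portions of the z
#'   faces) is perfectly insulating.  `"insulated"` is zero-flux
#'   everywhere.
#' @param dose_interval interval in s at which CEM43 dose is accumulated
#'   during treatment runs (temperature is treated as piecewise constant
#'   between samples).
#' @export
bhte_config <- function(dt = NULL, blood_temperature = 37,
                        blood_specific_heat = 3700,
                        initial_tissue = 37, initial_water = 23,
                        equilibration = 600,
                        boundary = c("dirichlet_z", "insulated"),
                        dose_interval = 1) {
  boundary <- match.arg(boundary)
  if (!is.null(dt)) stopifnot(dt > 0)
  stopifnot(equilibration >= 0, dose_interval > 0)
  structure(list(dt = dt, blood_temperature = blood_temperature,
                 blood_specific_heat = blood_specific_heat,
                 initial_tissue = initial_tissue,
                 initial_water = initial_water,
                 equilibration = equilibration,
                 boundary = boundary,
                 dose_interval = dose_interval),
            class = "bhte_config")
}

# Number of spatial dimensions actually resolved by the grid.
n_spatial_dims <- function(grid) sum(grid_dims(grid) > 1L)

#' Explicit stability bound for the bioheat stepper
#'
#' Forward-Euler bound min over voxels of rho*C / (2*d*k/dx^2 + w_b*C_b)
#' with d the number of resolved spatial dimensions; slightly conservative
#' because harmonic-mean face conductivities never exceed the local k.
#'
#' @param materials a `material_map`.
#' @param config a [bhte_config()].
#' @return maximum stable time step in s.
#' @export
stability_dt <- function(materials, config = bhte_config()) {
  g <- materials$grid
  d <- n_spatial_dims(g)
  tab <- materials$table
  rc <- tab$density * tab$specific_heat
  denom <- 2 * d * tab$conductivity / g$spacing^2 +
    tab$perfusion * config$blood_specific_heat
  present <- sort(unique(as.vector(materials$media)))
  min((rc / denom)[present])
}

resolve_dt <- function(materials, config) {
  bound <- stability_dt(materials, config)
  if (is.null(config$dt)) return(0.5 * bound)
  if (config$dt > bound)
    stop(sprintf("dt = %.4g s violates the stability bound %.4g s",
                 config$dt, bound))
  config$dt
}

#' Initial temperature field of a phantom
#'
#' Tissue voxels start at `initial_tissue`, water voxels at `initial_water`.
#'
#' @param materials a `material_map`.
#' @param config a [bhte_config()].
#' @return object of class `temperature_field` (`temperature` array in deg
#'   C, `grid`, `time` in s).
#' @export
initial_temperature <- function(materials, config = bhte_config()) {
  iw <- match("water", materials$table$medium)
  temp <- array(config$initial_tissue, dim = grid_dims(materials$grid))
  if (!is.na(iw)) temp[materials$media == iw] <- config$initial_water
  structure(list(temperature = temp, grid = materials$grid, time = 0),
            class = "temperature_field")
}

as_heat_array <- function(Q, grid) {
  if (is.null(Q)) return(array(0, dim = grid_dims(grid)))
  if (inherits(Q, "heat_field")) {
    if (!same_grid(Q$grid, grid)) return(resample_nearest(Q, grid))
    return(Q$q)
  }
  stopifnot(is.array(Q), all(dim(Q) == grid_dims(grid)))
  Q
}

# Nearest-voxel resampling of a heat field onto another grid.
resample_nearest <- function(Q, grid) {
  f <- Q$grid
  ix <- pmin(pmax(sapply(grid$x, function(v) which.min(abs(f$x - v))), 1L), f$nx)
  iy <- pmin(pmax(sapply(grid$y, function(v) which.min(abs(f$y - v))), 1L), f$ny)
  iz <- pmin(pmax(sapply(grid$z, function(v) which.min(abs(f$z - v))), 1L), f$nz)
  Q$q[ix, iy, iz, drop = FALSE]
}

run_bhte <- function(Tfield, Q, materials, config, duration, controller,
                     sensor_index, accumulate_dose = FALSE,
                     r_above = 0.5, r_below = 0.25,
                     snapshot_stride = 0L, source_on = TRUE) {
  g <- materials$grid
  stopifnot(all(dim(Tfield$temperature) == grid_dims(g)))
  dt <- resolve_dt(materials, config)
  nsteps <- max(1L, as.integer(ceiling(duration / dt)))
  qarr <- as_heat_array(Q, g)
  sensor0 <- (sensor_index[1] - 1L) +
    g$nx * ((sensor_index[2] - 1L) + g$ny * (sensor_index[3] - 1L))
  control <- !is.null(controller)
  dose_stride <- max(1L, as.integer(round(config$dose_interval / dt)))
  fixed <- array(FALSE, dim = grid_dims(g))
  if (config$boundary == "dirichlet_z" && g$nz > 1L) {
    iw <- match("water", materials$table$medium)
    water <- if (is.na(iw)) array(FALSE, grid_dims(g)) else
      materials$media == iw
    fixed[, , c(1L, g$nz)] <- water[, , c(1L, g$nz)]
  }
  res <- bhte_run_cpp(
    as.numeric(Tfield$temperature), as.numeric(qarr),
    as.numeric(material_property(materials, "density")),
    as.numeric(material_property(materials, "specific_heat")),
    as.numeric(material_property(materials, "conductivity")),
    as.numeric(material_property(materials, "perfusion")),
    grid_dims(g), g$spacing, dt, nsteps, Tfield$time,
    config$blood_temperature, config$blood_specific_heat,
    sensor0,
    control,
    if (control) controller$upper else 0,
    if (control) controller$lower else 0,
    if (control) isTRUE(controller$state) else isTRUE(source_on),
    as.logical(fixed),
    accumulate_dose, r_above, r_below, dose_stride,
    as.integer(snapshot_stride))
  res$dt <- dt
  res$grid <- g
  res
}

#' Source-free equilibration of the phantom
#'
#' Integrates the Pennes equation without heat source from the 37/23 deg C
#' initial condition for the configured duration, letting the water
#' standoff, skin and perfused tissue approach their joint equilibrium
#' before treatment.
#'
#' @param materials a `material_map`.
#' @param config a [bhte_config()].
#' @return a `temperature_field` at the end of equilibration.
#' @export
equilibrate <- function(materials, config = bhte_config()) {
  T0 <- initial_temperature(materials, config)
  if (config$equilibration <= 0) return(T0)
  ctr <- tumor_center_index(materials)
  res <- run_bhte(T0, NULL, materials, config, config$equilibration,
                  controller = NULL, sensor_index = ctr,
                  source_on = FALSE)
  structure(list(temperature = array(res$T, grid_dims(materials$grid)),
                 grid = materials$grid,
                 time = T0$time + res$dt * length(res$trace_t)),
            class = "temperature_field")
}

# Sensor voxel: tumor-region centroid if present, else the grid center.
tumor_center_index <- function(materials) {
  itu <- match("tumor", materials$table$medium)
  g <- materials$grid
  if (!is.na(itu) && any(materials$media == itu)) {
    w <- which(materials$media == itu, arr.ind = TRUE)
    ctr <- c(mean(g$x[w[, 1]]), mean(g$y[w[, 2]]), mean(g$z[w[, 3]]))
    return(nearest_voxel(g, ctr))
  }
  c((g$nx + 1L) %/% 2L, (g$ny + 1L) %/% 2L, (g$nz + 1L) %/% 2L)
}

#' Run a temperature-controlled treatment
#'
#' Explicit time stepping of the Pennes equation with the heat source gated
#' by a relay controller consulted every step with the sensor-voxel
#' temperature (default sensor: tumor center).  Records the full
#' (time, sensor temperature, source-on) trace and, by default, accumulates
#' the CEM43 dose map online at `config$dose_interval` sampling.
#'
#' @param T0 starting `temperature_field` (typically from [equilibrate()]).
#' @param Q `heat_field` (resampled by nearest voxel if on another grid),
#'   plain array, or `NULL` for no source.
#' @param controller a [hysteresis_controller()], or `NULL` to keep the
#'   source permanently on/off (`source_on`).
#' @param duration treatment duration in s.
#' @param config a [bhte_config()].
#' @param materials a `material_map`.
#' @param r_above,r_below CEM43 R-values above/below 43 deg C.
#' @param snapshot_stride store a full field snapshot every this many steps
#'   (0 = none).
#' @param accumulate_dose logical; accumulate the CEM43 map online.
#' @param source_on fixed source flag when `controller` is `NULL`.
#' @return object of class `temperature_history`: `trace` data.frame
#'   (`time_s`, `sensor_c`, `source_on`), `final` temperature field, `dose`
#'   CEM43 array (or NULL), optional `snapshots`, `dt`, `sensor_index`.
#' @export
run_treatment <- function(T0, Q, controller = hysteresis_controller(),
                          duration = 1200, config = bhte_config(),
                          materials, r_above = 0.5, r_below = 0.25,
                          snapshot_stride = 0L, accumulate_dose = TRUE,
                          source_on = TRUE) {
  stopifnot(inherits(T0, "temperature_field"), duration > 0,
            inherits(materials, "material_map"))
  if (!same_grid(T0$grid, materials$grid))
    stop("T0 and materials are defined on different grids")
  sensor_index <-
    if (!is.null(controller) && !is.null(controller$sensor))
      nearest_voxel(materials$grid, controller$sensor)
    else tumor_center_index(materials)
  res <- run_bhte(T0, Q, materials, config, duration,
                  controller = controller, sensor_index = sensor_index,
                  accumulate_dose = accumulate_dose,
                  r_above = r_above, r_below = r_below,
                  snapshot_stride = snapshot_stride, source_on = source_on)
  g <- materials$grid
  out <- list(
    trace = data.frame(time_s = res$trace_t, sensor_c = res$trace_T,
                       source_on = res$trace_on),
    final = structure(list(temperature = array(res$T, grid_dims(g)),
                           grid = g,
                           time = T0$time + res$dt * length(res$trace_t)),
                      class = "temperature_field"),
    dose = if (accumulate_dose) array(res$dose, grid_dims(g)) else NULL,
    snapshots = res$snapshots,
    dt = res$dt,
    sensor_index = sensor_index)
  class(out) <- "temperature_history"
  out
}

#' One forward-Euler update of the bioheat equation
#'
#' Single explicit step of diffusion (conservative flux form, harmonic-mean
#' interface conductivity), perfusion and source under the configured
#' boundary conditions.  Exposed for verification; the drivers use the same
#' kernel internally.
#'
#' @param Tfield a `temperature_field`.
#' @param Q effective heat source (`heat_field`, array or `NULL`).
#' @param dt time step in s; must satisfy the stability bound.
#' @param config a [bhte_config()].
#' @param materials a `material_map`.
#' @return the updated `temperature_field`.
#' @export
bhte_step <- function(Tfield, Q, dt, config = bhte_config(),
                      materials) {
  cfg <- config
  cfg$dt <- dt
  res <- run_bhte(Tfield, Q, materials, cfg, duration = dt,
                  controller = NULL,
                  sensor_index = tumor_center_index(materials),
                  source_on = TRUE)
  structure(list(temperature = array(res$T, grid_dims(materials$grid)),
                 grid = materials$grid, time = Tfield$time + dt),
            class = "temperature_field")
}

#' @export
print.temperature_history <- function(x, ...) {
  tr <- x$trace
  cat(sprintf(
    "temperature_history: %d steps (dt = %.3g s), sensor %.2f -> %.2f C, duty %.0f%%\n",
    nrow(tr), x$dt, tr$sensor_c[1], tr$sensor_c[nrow(tr)],
    100 * mean(tr$source_on)))
  invisible(x)
}

#' @export
plot.temperature_history <- function(x, ...) {
  tr <- x$trace
  plot(tr$time_s / 60, tr$sensor_c, type = "l",
       xlab = "time (min)", ylab = "sensor temperature (deg C)", ...)
  graphics::abline(h = c(41.5, 42), lty = 3, col = "grey40")
  invisible(x)
}
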