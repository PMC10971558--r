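#' Hysteresis (relay) temperature controller
#'
#' Two-state ON/OFF regulation emulating the experimental PID hardware: the
#' source is disabled when the sensor temperature strictly exceeds the upper
#' threshold and re-enabled when it strictly falls below the lower one;
#' inside the band the previous state is kept (hysteresis memory).  The
#' controller starts ON because heating is required to leave baseline.
#'
#' @param upper switch-off threshold in deg C (default 42).
#' @param lower switch-on threshold in deg C (default 41.5).
#' @param state initial state, `TRUE` = ON.
#' @param sensor optional length-3 sensor location in m (default: the
#'   treatment driver uses the tumor-center voxel).
#' @return object of class `hysteresis_controller`.
#' @export
hysteresis_controller <- function(upper = 42.0, lower = 41.5, state = TRUE,
                                  sensor = NULL) {
  stopifnot(is.numeric(upper), is.numeric(lower), is.logical(state))
  if (!(lower < upper)) stop("lower threshold must be below upper threshold")
  structure(list(upper = upper, lower = lower, state = state,
                 sensor = sensor),
            class = "hysteresis_controller")
}

#' Update a relay controller with a sensor reading
#'
#' @param ctrl a [hysteresis_controller()].
#' @param sensor_T sensor temperature in deg C (finite).
#' @return the controller with its `state` updated; query the commanded
#'   source flag as `ctrl$state`.
#' @export
controller_update <- function(ctrl, sensor_T) {
  stopifnot(inherits(ctrl, "hysteresis_controller"))
  if (!is.finite(sensor_T)) stop("sensor temperature must be finite")
  if (ctrl$state && sensor_T > ctrl$upper) ctrl$state <- FALSE
  else if (!ctrl$state && sensor_T < ctrl$lower) ctrl$state <- TRUE
  ctrl
}

#' @export
print.hysteresis_controller <- function(x, ...) {
  cat(sprintf("hysteresis_controller: ON below %.2f C, OFF above %.2f C, currently %s\n",
              x$lower, x$upper, if (x$state) "ON" else "OFF"))
  invisible(x)
}
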