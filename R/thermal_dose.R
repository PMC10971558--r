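#' Cumulative equivalent minutes at 43 deg C (CEM43)
#'
#' Thermal dose of a temperature history under the standard isoeffect
#' formalism: CEM43 = sum over intervals of (dt in minutes) * R^(43 - T),
#' with R = `r_above` (default 0.5) for T >= 43 deg C and `r_below`
#' (default 0.25) below, temperature piecewise constant per interval.
#'
#' @param history temperatures over time: a numeric vector (single sensor),
#'   a list of equally-spaced field snapshots (arrays), or a
#'   `temperature_history` with stored snapshots.
#' @param dt snapshot spacing in s.
#' @param r_above,r_below R-values above/below 43 deg C.
#' @return thermal dose in equivalent minutes at 43 deg C, with the shape
#'   of one snapshot (scalar for a sensor trace, array for field
#'   snapshots).
#' @export
cem43 <- function(history, dt, r_above = 0.5, r_below = 0.25) {
  if (inherits(history, "temperature_history")) {
    if (is.null(history$snapshots) || length(history$snapshots) == 0)
      stop("temperature_history carries no stored snapshots")
    history <- history$snapshots
  }
  if (missing(dt) || is.null(dt) || dt < 0) stop("dt must be non-negative")
  if (is.numeric(history)) history <- as.list(history)
  if (length(history) == 0) stop("empty temperature history")
  minutes <- dt / 60
  dose <- NULL
  for (temp in history) {
    r <- ifelse(temp >= 43, r_above, r_below)
    inc <- minutes * r^(43 - temp)
    dose <- if (is.null(dose)) inc else dose + inc
  }
  dose
}

#' Maximum thermal dose over a region
#'
#' @param map CEM43 dose map (numeric array).
#' @param mask logical array of the same shape selecting the region, or
#'   `NULL` for the whole map.
#' @return maximum CEM43 over the masked voxels.
#' @export
max_cem43 <- function(map, mask = NULL) {
  if (is.null(mask)) return(max(map))
  stopifnot(is.logical(mask), length(mask) == length(map))
  if (!any(mask)) stop("empty region mask")
  max(map[mask])
}

#' Summarise a thermal dose map
#'
#' @param map CEM43 dose array on a grid.
#' @param grid the `simulation_grid` the map lives on (for volumes).
#' @param mask optional logical region mask.
#' @return data.frame with max, mean, and the tissue volume (mm^3) at or
#'   above 1 CEM43.
#' @export
dose_summary <- function(map, grid, mask = NULL) {
  vals <- if (is.null(mask)) map else map[mask]
  voxel_mm3 <- (grid$spacing * 1e3)^3
  data.frame(max_cem43 = max(vals),
             mean_cem43 = mean(vals),
             volume_ge_1_mm3 = sum(vals >= 1) * voxel_mm3)
}
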