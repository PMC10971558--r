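#' Regular simulation grid
#'
#' Defines the voxel lattice shared by the acoustic and thermal solvers.
#' The z axis is the acoustic propagation axis with its origin at the
#' transducer apex; voxel centers are the sample points.  Lateral axes are
#' centered on the beam axis and forced to an odd voxel count so that the
#' axis itself is sampled.
#'
#' @param spacing voxel spacing in m (isotropic).
#' @param extent length-3 numeric, physical extent in m along (x, y, z).
#' @return An object of class `simulation_grid` with voxel-center
#'   coordinates `x`, `y`, `z` (m) and counts `nx`, `ny`, `nz`.
#' @export
simulation_grid <- function(spacing = 0.4e-3, extent = c(0.04, 0.04, 0.05)) {
  stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0,
            is.numeric(extent), length(extent) == 3L, all(extent > 0))
  nx <- 2L * as.integer(floor(extent[1] / (2 * spacing))) + 1L
  ny <- 2L * as.integer(floor(extent[2] / (2 * spacing))) + 1L
  nz <- max(1L, as.integer(round(extent[3] / spacing)))
  g <- list(
    spacing = spacing,
    nx = nx, ny = ny, nz = nz,
    x = (seq_len(nx) - (nx + 1) / 2) * spacing,
    y = (seq_len(ny) - (ny + 1) / 2) * spacing,
    z = (seq_len(nz) - 0.5) * spacing
  )
  class(g) <- "simulation_grid"
  g
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf("simulation_grid: %d x %d x %d voxels, %.3g mm spacing\n",
              x$nx, x$ny, x$nz, x$spacing * 1e3))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$spacing, b$spacing)) &&
    a$nx == b$nx && a$ny == b$ny && a$nz == b$nz
}

grid_dims <- function(g) c(g$nx, g$ny, g$nz)

#' Nearest voxel index for a physical location
#'
#' @param grid a [simulation_grid()].
#' @param location length-3 numeric position in m.
#' @return integer length-3 voxel index (1-based).
#' @export
nearest_voxel <- function(grid, location) {
  stopifnot(length(location) == 3L)
  idx <- c(which.min(abs(grid$x - location[1])),
           which.min(abs(grid$y - location[2])),
           which.min(abs(grid$z - location[3])))
  if (abs(grid$x[idx[1]] - location[1]) > grid$spacing ||
      abs(grid$y[idx[2]] - location[2]) > grid$spacing ||
      abs(grid$z[idx[3]] - location[3]) > grid$spacing)
    stop("location lies outside the grid")
  idx
}

#' Acoustic and thermal material properties of the simulated media
#'
#' Literature values for degassed water, rat skin, subcutaneous tumor and
#' skeletal muscle used by both solvers.  Attenuation is expressed in
#' Np/(m*MHz), i.e. it scales linearly with frequency; water is lossless and
#' unperfused.
#'
#' @return data.frame with one row per medium: `density` (kg/m^3),
#'   `sound_speed` (m/s), `attenuation` (Np/(m*MHz)), `conductivity`
#'   (W/(m*C)), `specific_heat` (J/(kg*C)), `perfusion` (kg/(m^3*s)).
#' @export
material_table <- function() {
  data.frame(
    medium        = c("water", "skin", "tumor", "muscle"),
    density       = c(1000, 1060, 1060, 1060),
    sound_speed   = c(1482, 1624, 1560, 1588),
    attenuation   = c(0, 21.2, 9.32, 7.1),
    conductivity  = c(0.627, 0.5, 0.5, 0.52),
    specific_heat = c(4118, 3700, 3700, 3700),
    perfusion     = c(0, 2.0, 20, 0.7),
    stringsAsFactors = FALSE
  )
}

#' Layered phantom geometry
#'
#' A water standoff, a thin skin layer, and a spherical tumor embedded in
#' muscle, stacked along the propagation axis.  By default the tumor center
#' sits at the geometric focus and the tumor's proximal pole touches the
#' underside of the skin, so `water_standoff = focal_length - skin -
#' tumor_radius`.
#'
#' @param focal_length transducer radius of curvature in m, used to place
#'   the default tumor center at the focus.
#' @param skin_thickness skin layer thickness in m (default 0.8 mm).
#' @param tumor_diameter tumor diameter in m (default 6 mm; set 0 for a
#'   tumor-free phantom).
#' @param water_standoff apex-to-skin distance in m; default places the
#'   focus at the tumor center.
#' @param tumor_center length-3 position in m; default on axis at the focus.
#' @export
layered_phantom <- function(focal_length = 31.5e-3,
                            skin_thickness = 0.8e-3,
                            tumor_diameter = 6e-3,
                            water_standoff = NULL,
                            tumor_center = NULL) {
  stopifnot(skin_thickness > 0, tumor_diameter >= 0, focal_length > 0)
  if (is.null(water_standoff))
    water_standoff <- focal_length - skin_thickness - tumor_diameter / 2
  if (water_standoff < 0) stop("water_standoff must be non-negative")
  if (is.null(tumor_center)) tumor_center <- c(0, 0, focal_length)
  ph <- list(water_standoff = water_standoff,
             skin_thickness = skin_thickness,
             tumor_diameter = tumor_diameter,
             tumor_center = tumor_center)
  class(ph) <- "layered_phantom"
  ph
}

#' Voxelize a layered phantom into a material map
#'
#' Assigns every voxel of `grid` to exactly one medium of `table`: water up
#' to the skin surface, the skin layer, then muscle, with a spherical tumor
#' carved out around the configured center.  Deterministic.
#'
#' @param phantom a [layered_phantom()].
#' @param grid a [simulation_grid()].
#' @param table material property table, one row per medium
#'   (default [material_table()]).
#' @return A `material_map`: the grid, an integer `media` array indexing
#'   rows of `table`, and the table itself.  Use [material_property()] to
#'   expand a property to a per-voxel array.
#' @export
build_phantom_fixture <- function(phantom, grid, table = material_table()) {
  stopifnot(inherits(phantom, "layered_phantom"),
            inherits(grid, "simulation_grid"))
  z_skin <- phantom$water_standoff
  z_tissue <- z_skin + phantom$skin_thickness
  iw <- match("water", table$medium)
  isk <- match("skin", table$medium)
  itu <- match("tumor", table$medium)
  imu <- match("muscle", table$medium)
  if (anyNA(c(iw, isk, itu, imu)))
    stop("table must contain water, skin, tumor and muscle rows")

  med_z <- ifelse(grid$z < z_skin, iw, ifelse(grid$z < z_tissue, isk, imu))
  media <- array(rep(med_z, each = grid$nx * grid$ny),
                 dim = grid_dims(grid))
  if (phantom$tumor_diameter > 0) {
    ctr <- phantom$tumor_center
    r2 <- (phantom$tumor_diameter / 2)^2
    if (ctr[3] + phantom$tumor_diameter / 2 > max(grid$z) + grid$spacing / 2)
      stop("tumor geometry exceeds the grid")
    dx2 <- (grid$x - ctr[1])^2
    dy2 <- (grid$y - ctr[2])^2
    dz2 <- (grid$z - ctr[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    tissue <- media == imu
    media[inside & tissue] <- itu
  }
  structure(list(grid = grid, media = media, table = table),
            class = "material_map")
}

#' Uniform single-medium material map
#'
#' Convenience constructor for water-only propagation runs and solver tests.
#'
#' @param grid a [simulation_grid()].
#' @param medium medium name, a row of `table`.
#' @param table material property table.
#' @export
uniform_materials <- function(grid, medium = "water",
                              table = material_table()) {
  i <- match(medium, table$medium)
  if (is.na(i)) stop("unknown medium: ", medium)
  media <- array(i, dim = grid_dims(grid))
  structure(list(grid = grid, media = media, table = table),
            class = "material_map")
}

#' Per-voxel property array of a material map
#'
#' @param map a `material_map`.
#' @param name one of `"density"`, `"sound_speed"`, `"attenuation"`,
#'   `"conductivity"`, `"specific_heat"`, `"perfusion"`.
#' @return numeric array with the grid's dimensions.
#' @export
material_property <- function(map, name) {
  stopifnot(inherits(map, "material_map"))
  if (!name %in% names(map$table) || name == "medium")
    stop("unknown material property: ", name)
  array(map$table[[name]][map$media], dim = dim(map$media))
}

#' @export
print.material_map <- function(x, ...) {
  tab <- table(factor(x$table$medium[x$media], levels = x$table$medium))
  cat("material_map on ", x$grid$nx, " x ", x$grid$ny, " x ", x$grid$nz,
      " voxels\n", sep = "")
  print(tab)
  invisible(x)
}
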