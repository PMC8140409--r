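#' Regular latitude-longitude grid specification
#'
#' A `grid_spec` holds the cell-center coordinates of a regular geographic
#' grid. Cells are half-open boxes `[center - res/2, center + res/2)`;
#' coordinates are cell centers, latitudes ascending in degrees north,
#' longitudes ascending in degrees east on the `[-180, 180)` convention
#' (inputs on `[0, 360)` are rotated on read).
#'
#' @param lat Numeric vector of cell-center latitudes, ascending, regular.
#' @param lon Numeric vector of cell-center longitudes, ascending, regular.
#' @param tol Tolerance (degrees) for spacing regularity.
#' @return An object of class `grid_spec` with fields `lat`, `lon`, `res`.
#' @examples
#' g <- grid_spec(lat = seq(35, 60, by = 0.5), lon = seq(-10, 30, by = 0.5))
#' @export
grid_spec <- function(lat, lon, tol = 1e-9) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (length(lat) < 1 || length(lon) < 1)
    stop_stage("grid", "empty coordinate vector")
  res_lat <- if (length(lat) > 1) diff(lat) else NULL
  res_lon <- if (length(lon) > 1) diff(lon) else NULL
  steps <- c(res_lat, res_lon)
  if (length(steps) == 0) stop_stage("grid", "cannot infer resolution from a 1x1 grid")
  res <- stats::median(steps)
  if (res <= 0) stop_stage("grid", "coordinates must be ascending")
  if (any(abs(steps - res) > tol))
    stop_stage("grid", sprintf("irregular grid spacing beyond tolerance %g degrees", tol))
  if (any(lat < -90 | lat > 90)) stop_stage("grid", "latitudes outside [-90, 90]")
  if (any(lat - res / 2 < -90) || any(lat + res / 2 > 90))
    stop_stage("grid", "cells cross a pole")
  if (any(lon >= 360) || any(lon < -180)) stop_stage("grid", "longitudes outside [-180, 360)")
  if (any(lon >= 180)) lon <- ((lon + 180) %% 360) - 180   # rotate 0..360 inputs
  if (is.unsorted(lon)) stop_stage("grid", "longitudes not ascending after rotation to [-180, 180)")
  structure(list(lat = lat, lon = lon, res = res), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells at %.4g deg, lat [%.3f, %.3f], lon [%.3f, %.3f]\n",
              length(x$lat), length(x$lon), x$res,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' @method all.equal grid_spec
#' @export
all.equal.grid_spec <- function(target, current, tolerance = 1e-9, ...) {
  ok <- length(target$lat) == length(current$lat) &&
    length(target$lon) == length(current$lon) &&
    max(abs(target$lat - current$lat)) <= tolerance &&
    max(abs(target$lon - current$lon)) <= tolerance
  if (ok) TRUE else "grids differ"
}

same_grid <- function(a, b, tol = 1e-9) isTRUE(all.equal.grid_spec(a, b, tolerance = tol))

assert_same_grid <- function(stage, ...) {
  grids <- list(...)
  for (i in seq_along(grids)[-1])
    if (!same_grid(grids[[1]], grids[[i]]))
      stop_stage(stage, "inputs are not on the same grid")
  invisible(TRUE)
}

#' Spherical cell areas of a regular grid
#'
#' Computes the area of every grid cell on a sphere of radius 6371 km:
#' \eqn{A = R^2 \Delta\lambda (\sin\varphi_{top} - \sin\varphi_{bottom})}
#' with cell edges at center +- resolution/2. Areas are constant along a
#' latitude row and decrease towards the poles; they support the per-km2
#' normalisation of mortality maps.
#'
#' @param grid A [grid_spec()].
#' @return An `area_field`: list with `grid` and an `nlat x nlon` matrix
#'   `area` in km2.
#' @examples
#' a <- cell_areas(grid_spec(lat = c(-0.5, 0.5), lon = c(0, 1)))
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  half <- grid$res / 2
  top <- grid$lat + half
  bot <- grid$lat - half
  if (any(top > 90 + 1e-12) || any(bot < -90 - 1e-12))
    stop_stage("grid", "cells cross a pole")
  dlam <- grid$res * pi / 180
  row_area <- EARTH_RADIUS_KM^2 * dlam *
    (sin(top * pi / 180) - sin(bot * pi / 180))
  area <- matrix(row_area, nrow = length(grid$lat), ncol = length(grid$lon))
  structure(list(grid = grid, area = area), class = "area_field")
}
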