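#' Define a regular longitude/latitude analysis grid
#'
#' A grid spec fixes the raster geometry every layer, occurrence set and
#' prediction map in an analysis shares: `n_rows` latitude bands by `n_cols`
#' longitude bands of `cell_size` degrees, anchored at the south-west corner
#' (`lon_min`, `lat_min`). Values are cell-registered: a layer value applies
#' to the whole cell and exported coordinates are cell centres. Row 1 is the
#' southernmost band, column 1 the westernmost.
#'
#' The default cell size of 1/6 degree (10 arc-minutes) matches the
#' resolution commonly used for continental-scale habitat suitability
#' modelling.
#'
#' @param n_rows,n_cols Grid dimensions (latitude bands, longitude bands).
#' @param lon_min,lat_min South-west corner of the grid, decimal degrees
#'   (WGS84).
#' @param cell_size Cell edge in degrees. Default `1/6` (10 arc-min).
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(60, 60, lon_min = 60, lat_min = 30)
#' cell_centers(spec)
#' @export
grid_spec <- function(n_rows, n_cols, lon_min = 0, lat_min = 0,
                      cell_size = 1 / 6) {
  stopifnot(
    length(n_rows) == 1, length(n_cols) == 1,
    n_rows >= 1, n_cols >= 1,
    n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
    cell_size > 0
  )
  lat_max <- lat_min + n_rows * cell_size
  if (lat_min < -90 || lat_max > 90 + 1e-9) {
    rlang::abort("grid latitudes must lie within [-90, 90]")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      lon_min = lon_min, lat_min = lat_min, cell_size = cell_size
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %.4f deg, SW corner (%.4f, %.4f)\n",
    x$n_rows, x$n_cols, x$cell_size, x$lon_min, x$lat_min
  ))
  invisible(x)
}

n_cells <- function(spec) spec$n_rows * spec$n_cols

#' Cell centres of a grid
#'
#' @param spec A [grid_spec()].
#' @return A tibble with one row per cell: `cell_id` (row-major, row 1 =
#'   southernmost), `row`, `col`, `lon`, `lat` (cell-centre coordinates).
#' @export
cell_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  row <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  col <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  tibble::tibble(
    cell_id = (row - 1L) * spec$n_cols + col,
    row = row, col = col,
    lon = spec$lon_min + (col - 0.5) * spec$cell_size,
    lat = spec$lat_min + (row - 0.5) * spec$cell_size
  )
}

#' Locate coordinates on a grid
#'
#' Maps longitude/latitude pairs to grid row/column indices. Points outside
#' the grid extent get `NA` indices. Points exactly on the eastern or
#' northern edge are assigned to the last cell.
#'
#' @param lon,lat Coordinate vectors, decimal degrees.
#' @param spec A [grid_spec()].
#' @return A tibble with columns `row`, `col`, `cell_id` (`NA` off-grid).
#' @export
locate_cells <- function(lon, lat, spec) {
  stopifnot(inherits(spec, "grid_spec"), length(lon) == length(lat))
  col <- floor((lon - spec$lon_min) / spec$cell_size) + 1
  row <- floor((lat - spec$lat_min) / spec$cell_size) + 1
  # close the top/right edges
  col[lon == spec$lon_min + spec$n_cols * spec$cell_size] <- spec$n_cols
  row[lat == spec$lat_min + spec$n_rows * spec$cell_size] <- spec$n_rows
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(
    row = as.integer(row), col = as.integer(col),
    cell_id = (as.integer(row) - 1L) * spec$n_cols + as.integer(col)
  )
}

#' Mean Earth radius (km) used for spherical cell areas
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Spherical area of grid cells at given latitudes
#'
#' Area of a lon/lat cell on the sphere:
#' \deqn{A = R^2 \, \Delta\lambda \,(\sin\varphi_{top} - \sin\varphi_{bottom})}
#' with \eqn{R} the mean Earth radius (6371.0088 km). The area shrinks with
#' the cosine of latitude, which is what makes high-latitude cells count less
#' in habitat-area totals.
#'
#' @param lat_center Vector of cell-centre latitudes, degrees.
#' @param spec A [grid_spec()] supplying the cell size.
#' @return Cell areas in km², same length as `lat_center`.
#' @examples
#' # a 10 arc-min cell on the equator is ~344 km^2
#' cell_area_km2(0, grid_spec(1, 1, 0, -1 / 12))
#' @export
cell_area_km2 <- function(lat_center, spec) {
  stopifnot(inherits(spec, "grid_spec"), all(abs(lat_center) <= 90))
  half <- spec$cell_size / 2
  top <- pmin(lat_center + half, 90)
  bot <- pmax(lat_center - half, -90)
  dlam <- spec$cell_size * pi / 180
  EARTH_RADIUS_KM^2 * dlam * (sin(top * pi / 180) - sin(bot * pi / 180))
}

#' Round half away from zero
#'
#' Presentation rounding used for area tables: 0.005 rounds to 0.01,
#' -27.425 to -27.43 (base R's `round()` rounds half to even). Internal
#' computations always use full precision; this is applied only when a
#' table is printed or written.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
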