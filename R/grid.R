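#' Regular lon/lat grid specification
#'
#' The grid doubles as the point array used for all area estimation:
#' every mask, field and overlap statistic in the package lives on a
#' `grid_spec`. Cell centers sit at `origin + (index + 0.5) * resolution`
#' in each axis; cell membership is always decided at the center point.
#' Coordinates are WGS-84 lon/lat treated as planar (the study regions
#' span a few degrees, and areas are reported as cell counts, not km2).
#'
#' @param lon_min,lat_min lower-left corner of the grid, decimal degrees.
#' @param n_cols,n_rows number of cells along longitude and latitude.
#' @param resolution cell size in degrees.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(lon_min, lat_min, n_cols, n_rows, resolution = 0.05) {
  stopifnot(n_cols >= 2, n_rows >= 2, resolution > 0)
  structure(
    list(lon_min = lon_min, lat_min = lat_min,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         resolution = resolution),
    class = "grid_spec"
  )
}

#' Smallest grid covering a bounding box
#'
#' @param lon_min,lon_max,lat_min,lat_max bounding box, decimal degrees.
#' @param resolution cell size in degrees.
#' @return a [grid_spec()].
#' @export
grid_for_bbox <- function(lon_min, lon_max, lat_min, lat_max, resolution = 0.05) {
  stopifnot(lon_max > lon_min, lat_max > lat_min)
  grid_spec(lon_min, lat_min,
            n_cols = ceiling((lon_max - lon_min) / resolution - 1e-9),
            n_rows = ceiling((lat_max - lat_min) / resolution - 1e-9),
            resolution = resolution)
}

n_cells <- function(grid) grid$n_cols * grid$n_rows

#' Cell-center coordinates of a grid
#'
#' Row-major order: longitude varies fastest, latitude increases across
#' rows. All vectors of cell values in the package follow this order.
#'
#' @param grid a [grid_spec()].
#' @return data.frame with columns `lon`, `lat`, one row per cell.
#' @export
grid_centers <- function(grid) {
  lon <- grid$lon_min + (seq_len(grid$n_cols) - 0.5) * grid$resolution
  lat <- grid$lat_min + (seq_len(grid$n_rows) - 0.5) * grid$resolution
  data.frame(lon = rep(lon, times = grid$n_rows),
             lat = rep(lat, each = grid$n_cols))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Gridded field of one variable
#'
#' @param grid a [grid_spec()].
#' @param values numeric vector, one value per cell in row-major order.
#' @param variable label of the variable.
#' @param units unit string (informational).
#' @return an object of class `mr_field`.
#' @export
new_field <- function(grid, values, variable = "value", units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.numeric(values)
  if (length(values) != n_cells(grid))
    stop("field length ", length(values), " != cell count ", n_cells(grid))
  if (!all(is.finite(values)))
    stop("field '", variable, "' contains non-finite values")
  structure(list(grid = grid, values = values, variable = variable, units = units),
            class = "mr_field")
}

#' Boolean spatial mask over a grid
#'
#' The unit of all area and overlap computation: area is the count of
#' true cells, exactly the point-count approximation of irregular
#' regions used throughout the overlap statistics.
#'
#' @param grid a [grid_spec()].
#' @param membership logical vector, one flag per cell (row-major).
#' @param label mask label.
#' @return an object of class `mr_mask`.
#' @export
new_mask <- function(grid, membership, label = "") {
  stopifnot(inherits(grid, "grid_spec"))
  membership <- as.logical(membership)
  if (length(membership) != n_cells(grid))
    stop("mask length ", length(membership), " != cell count ", n_cells(grid))
  if (anyNA(membership)) stop("mask membership contains NA")
  structure(list(grid = grid, membership = membership, label = label),
            class = "mr_mask")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.4g deg, origin (%.3f, %.3f)\n",
              x$n_cols, x$n_rows, x$resolution, x$lon_min, x$lat_min))
  invisible(x)
}

#' @export
print.mr_field <- function(x, ...) {
  cat(sprintf("field '%s'%s on %d x %d grid: range [%.4g, %.4g]\n",
              x$variable, if (nzchar(x$units)) paste0(" (", x$units, ")") else "",
              x$grid$n_cols, x$grid$n_rows, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.mr_mask <- function(x, ...) {
  cat(sprintf("mask '%s' on %d x %d grid: %d of %d cells\n",
              x$label, x$grid$n_cols, x$grid$n_rows,
              sum(x$membership), length(x$membership)))
  invisible(x)
}

# Bilinear interpolation of a gridded field at arbitrary points,
# clamped to the grid's center lattice at the borders.
field_at <- function(field, lon, lat) {
  g <- field$grid
  fx <- (lon - g$lon_min) / g$resolution - 0.5
  fy <- (lat - g$lat_min) / g$resolution - 0.5
  fx <- pmin(pmax(fx, 0), g$n_cols - 1)
  fy <- pmin(pmax(fy, 0), g$n_rows - 1)
  x0 <- pmin(floor(fx), g$n_cols - 2); x1 <- x0 + 1
  y0 <- pmin(floor(fy), g$n_rows - 2); y1 <- y0 + 1
  wx <- fx - x0; wy <- fy - y0
  idx <- function(i, j) j * g$n_cols + i + 1
  v <- field$values
  v[idx(x0, y0)] * (1 - wx) * (1 - wy) + v[idx(x1, y0)] * wx * (1 - wy) +
    v[idx(x0, y1)] * (1 - wx) * wy + v[idx(x1, y1)] * wx * wy
}
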