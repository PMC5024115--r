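#' Define a scene grid (equidistant cylindrical)
#'
#' Pixels are laid out on a plate carree (equidistant cylindrical) grid with
#' the same angular step in latitude and longitude, derived from the nominal
#' pixel size in metres (degrees = pixel_m / 111320). Row 1 is the
#' northernmost row. Pixel area is fixed at 1/16 km^2 everywhere for all area
#' accounting, regardless of latitude; this matches the native 250-m pixel
#' convention used throughout the package.
#'
#' @param lat_min,lat_max,lon_min,lon_max grid bounds in decimal degrees.
#' @param pixel_m nominal pixel size in metres (default 250).
#' @return an object of class `scene_grid` with fields `ny`, `nx`, the
#'   bounds, `step_deg`, `pixel_m` and `pixel_area_km2`.
#' @examples
#' g <- scene_grid(9.8, 9.9, 115.4, 115.5)
#' g$pixel_area_km2  # 0.0625
#' @export
scene_grid <- function(lat_min, lat_max, lon_min, lon_max, pixel_m = 250) {
  stopifnot(is.numeric(pixel_m), length(pixel_m) == 1L, pixel_m > 0)
  if (lat_max <= lat_min || lon_max <= lon_min)
    stop("grid bounds must satisfy lat_max > lat_min and lon_max > lon_min")
  step <- pixel_m / 111320
  ny <- max(1L, as.integer(round((lat_max - lat_min) / step)))
  nx <- max(1L, as.integer(round((lon_max - lon_min) / step)))
  structure(list(
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    pixel_m = pixel_m, step_deg = step,
    ny = ny, nx = nx,
    pixel_area_km2 = 1 / 16
  ), class = "scene_grid")
}

#' @export
print.scene_grid <- function(x, ...) {
  cat(sprintf("<scene_grid> %d x %d pixels (%.0f m), lat [%.4f, %.4f], lon [%.4f, %.4f]\n",
              x$ny, x$nx, x$pixel_m, x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

#' Pixel-centre coordinates of a grid
#'
#' @param grid a `scene_grid`.
#' @return `grid_lat()` gives the latitude of each row (row 1 northernmost);
#'   `grid_lon()` the longitude of each column.
#' @export
grid_lat <- function(grid) {
  grid$lat_max - (seq_len(grid$ny) - 0.5) * grid$step_deg
}

#' @rdname grid_lat
#' @export
grid_lon <- function(grid) {
  grid$lon_min + (seq_len(grid$nx) - 0.5) * grid$step_deg
}

#' Create an empty (all-FALSE) binary mask on a grid
#'
#' Binary masks are plain logical matrices of dimension `ny x nx` carrying
#' the grid as an attribute.
#'
#' @param grid a `scene_grid`.
#' @export
empty_mask <- function(grid) {
  m <- matrix(FALSE, grid$ny, grid$nx)
  attr(m, "grid") <- grid
  m
}

mask_on_grid <- function(values, grid) {
  stopifnot(is.logical(values), nrow(values) == grid$ny, ncol(values) == grid$nx)
  attr(values, "grid") <- grid
  values
}

#' Area of a binary mask in km^2
#'
#' Pixel count times the fixed 1/16 km^2 pixel area.
#' @param mask logical matrix.
#' @export
mask_area_km2 <- function(mask) {
  sum(mask, na.rm = TRUE) / 16
}
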