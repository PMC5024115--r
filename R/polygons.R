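# Polygon handling. Polygons are lists of rings; each ring is a two-column
# matrix of (lon, lat) vertices. Multiple rings combine by the even-odd rule,
# so holes are expressed as interior rings. A bare two-column matrix is
# accepted wherever a polygon is expected.

#' Coerce to the internal polygon representation
#'
#' @param x a two-column (lon, lat) matrix, a list of such matrices (rings),
#'   or an existing `reef_polygon`.
#' @return a `reef_polygon`: a list of ring matrices.
#' @export
as_polygon <- function(x) {
  if (inherits(x, "reef_polygon")) return(x)
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || length(x) == 0L)
    return(structure(list(), class = "reef_polygon"))
  rings <- lapply(x, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L) stop("polygon rings must be two-column (lon, lat) matrices")
    storage.mode(r) <- "double"
    dimnames(r) <- NULL
    # drop an explicit closing vertex; rings are implicitly closed
    n <- nrow(r)
    if (n > 1L && all(r[1L, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    r
  })
  structure(rings, class = "reef_polygon")
}

ring_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_area_deg2 <- function(poly) {
  sum(vapply(poly, ring_area, numeric(1)))
}

# Even-odd ray-casting containment of points in one ring, vectorised over
# points. Boundary behaviour follows the half-open convention of the
# crossing test; callers relying on exact-boundary pixels should inset or
# outset vertices slightly.
ring_contains <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  if (n < 3L) return(inside)
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- which((yi > py) != (yj > py))
    if (length(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      hit <- crosses[px[crosses] < xint]
      inside[hit] <- !inside[hit]
    }
    j <- i
  }
  inside
}

#' Test points for polygon containment (even-odd rule)
#'
#' @param lon,lat numeric vectors of point coordinates.
#' @param polygon anything accepted by [as_polygon()].
#' @return logical vector.
#' @export
points_in_polygon <- function(lon, lat, polygon) {
  poly <- as_polygon(polygon)
  inside <- logical(length(lon))
  for (ring in poly) {
    inside <- xor(inside, ring_contains(lon, lat, ring))
  }
  inside
}

#' Rasterize a polygon onto a grid by pixel-centre containment
#'
#' A pixel is set if and only if its centre lies inside the polygon under the
#' even-odd rule. A degenerate (zero-area) polygon yields an empty mask with
#' a warning; an empty polygon list yields an empty mask silently.
#'
#' @param polygon anything accepted by [as_polygon()].
#' @param grid a [scene_grid()].
#' @return a logical `ny x nx` mask.
#' @export
rasterize_polygon <- function(polygon, grid) {
  poly <- as_polygon(polygon)
  out <- empty_mask(grid)
  if (length(poly) == 0L) return(out)
  if (polygon_area_deg2(poly) == 0) {
    warning("degenerate (zero-area) polygon; returning empty mask")
    return(out)
  }
  lats <- grid_lat(grid)
  lons <- grid_lon(grid)
  # restrict the candidate window to the polygon bounding box
  bb <- do.call(rbind, lapply(poly, function(r) {
    c(min(r[, 1L]), max(r[, 1L]), min(r[, 2L]), max(r[, 2L]))
  }))
  lon_rng <- c(min(bb[, 1L]), max(bb[, 2L]))
  lat_rng <- c(min(bb[, 3L]), max(bb[, 4L]))
  cols <- which(lons >= lon_rng[1L] & lons <= lon_rng[2L])
  rows <- which(lats >= lat_rng[1L] & lats <= lat_rng[2L])
  if (!length(cols) || !length(rows)) return(out)
  px <- rep(lons[cols], each = length(rows))
  py <- rep(lats[rows], times = length(cols))
  inside <- points_in_polygon(px, py, poly)
  sub <- matrix(inside, nrow = length(rows), ncol = length(cols))
  out[rows, cols] <- sub
  out
}

#' Build a circular polygon around a centre point
#'
#' Convenience for reef outlines and plume blobs: a regular polygon
#' approximating a circle of the given radius. The radius is converted to
#' degrees with the same 111.32 km/degree convention as the grid, so circles
#' are circular in grid (pixel) space.
#'
#' @param lon,lat centre in degrees.
#' @param radius_km radius in kilometres.
#' @param n number of vertices (default 72).
#' @export
circle_polygon <- function(lon, lat, radius_km, n = 72L) {
  r_deg <- radius_km / 111.32
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  as_polygon(cbind(lon + r_deg * cos(th), lat + r_deg * sin(th)))
}
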