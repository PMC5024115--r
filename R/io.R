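# Plain-text I/O. The grading and deployment environments carry no
# binary-raster libraries, so gridded data are exchanged as CSV grids with a
# JSON sidecar describing the grid, polygons as GeoJSON, and configs as
# JSON.

grid_to_list <- function(grid) {
  grid[c("lat_min", "lat_max", "lon_min", "lon_max", "pixel_m")]
}

grid_from_list <- function(x) {
  scene_grid(x$lat_min, x$lat_max, x$lon_min, x$lon_max, x$pixel_m)
}

#' Read/write a binary mask as a CSV 0/1 grid
#'
#' The grid metadata travels in a `<path>.grid.json` sidecar.
#'
#' @param mask logical matrix with a grid attribute (or pass `grid`).
#' @param path CSV file path.
#' @param grid the mask's grid if not attached.
#' @export
write_mask_csv <- function(mask, path, grid = NULL) {
  if (is.null(grid)) grid <- attr(mask, "grid")
  data.table::fwrite(data.table::as.data.table(mask + 0L), path,
                     col.names = FALSE)
  if (!is.null(grid))
    jsonlite::write_json(grid_to_list(grid), paste0(path, ".grid.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  m <- as.matrix(data.table::fread(path, header = FALSE)) > 0L
  dimnames(m) <- NULL
  sidecar <- paste0(path, ".grid.json")
  if (file.exists(sidecar)) {
    attr(m, "grid") <- grid_from_list(jsonlite::read_json(sidecar))
  }
  m
}

#' Write/read a scene series as a directory of text files
#'
#' Layout: `meta.json` (grid, dates, solar zenith), one `<band>.csv` per
#' band and `cloud.csv`, each with one row per date and one column per pixel
#' in column-major order. Intended for small scenes and the CLI; large
#' series should be generated in memory.
#'
#' @param series a `scene_series`.
#' @param dir output directory (created if needed).
#' @export
write_scene_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(grid = grid_to_list(series$grid),
               dates = format(series$dates),
               solar_zenith = series$solar_zenith)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  nt <- length(series$dates)
  for (b in names(series$bands)) {
    flat <- t(apply(series$bands[[b]], 3L, identity))
    dim(flat) <- c(nt, series$grid$ny * series$grid$nx)
    data.table::fwrite(data.table::as.data.table(flat),
                       file.path(dir, paste0(b, ".csv")), col.names = FALSE)
  }
  flat <- t(apply(series$cloud, 3L, identity)) + 0L
  dim(flat) <- c(nt, series$grid$ny * series$grid$nx)
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(dir, "cloud.csv"), col.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene_series
#' @export
read_scene_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  grid <- grid_from_list(as.list(meta$grid))
  dates <- as.Date(meta$dates)
  nt <- length(dates)
  read_band <- function(f, logical = FALSE) {
    m <- as.matrix(data.table::fread(file.path(dir, f), header = FALSE))
    arr <- array(t(m), c(grid$ny, grid$nx, nt))
    if (logical) arr > 0 else arr
  }
  bands <- lapply(paste0(BAND_NAMES, ".csv"), read_band)
  names(bands) <- BAND_NAMES
  structure(list(grid = grid, dates = dates, bands = bands,
                 cloud = read_band("cloud.csv", logical = TRUE),
                 solar_zenith = as.numeric(meta$solar_zenith)),
            class = "scene_series")
}

#' Read polygons from GeoJSON
#'
#' Supports Feature/FeatureCollection with Polygon or MultiPolygon
#' geometries. Coordinates are (lon, lat). Feature properties are attached
#' to each polygon.
#'
#' @param path GeoJSON file.
#' @return a list of `reef_polygon`s; each carries a `properties` attribute.
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else stop("expected a GeoJSON Feature or FeatureCollection")
  lapply(feats, function(f) {
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type))
    mats <- lapply(rings, function(r) {
      do.call(rbind, lapply(r, function(pt) c(pt[[1L]], pt[[2L]])))
    })
    poly <- as_polygon(mats)
    attr(poly, "properties") <- f$properties
    poly
  })
}

#' Write polygons to GeoJSON
#'
#' @param polys list of polygons ([as_polygon()] input); names and per-item
#'   `properties` attributes become feature properties.
#' @param path output file.
#' @export
write_geojson_polygons <- function(polys, path) {
  feats <- lapply(seq_along(polys), function(i) {
    poly <- as_polygon(polys[[i]])
    rings <- lapply(poly, function(r) {
      r <- rbind(r, r[1L, , drop = FALSE])  # close the ring
      lapply(seq_len(nrow(r)), function(j) c(r[j, 1L], r[j, 2L]))
    })
    props <- attr(polys[[i]], "properties")
    if (is.null(props)) props <- list()
    nm <- names(polys)[i]
    if (!is.null(nm) && nzchar(nm)) props$name <- nm
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cloudmask overrides from GeoJSON
#'
#' Features must carry a `mode` property (`force_clear` or `force_cloud`)
#' and may carry `date_start`/`date_end`.
#'
#' @param path GeoJSON file.
#' @return a list of [mask_override()]s.
#' @export
read_overrides_geojson <- function(path) {
  polys <- read_geojson_polygons(path)
  lapply(polys, function(p) {
    props <- attr(p, "properties")
    if (is.null(props$mode)) stop("override feature lacks a 'mode' property")
    mask_override(p, mode = props$mode,
                  date_start = props$date_start, date_end = props$date_end)
  })
}
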