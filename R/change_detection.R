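# Change detection: shallow-water mapping from red-band exceedance counts,
# per-pixel NIR temporal trends, and island detection by thresholding the
# trend grid.

#' Detection thresholds and guards
#'
#' Defaults follow the calibrated operating point of the analysis chain:
#' shallow water is any pixel whose red-band reflectance exceeds 0.005 in at
#' least 20 cloud-free passes of the reference year; new islands are pixels
#' whose NIR (859 nm) reflectance trend exceeds 0.013 per year, a threshold
#' chosen so that no deep-water pixel is flagged; islands smaller than about
#' 0.06 km^2 (one native pixel) are below the method's resolution limit.
#'
#' @param shallow_threshold red-band exceedance level (default 0.005).
#' @param shallow_min_count minimum number of exceeding passes (default 20).
#' @param slope_threshold NIR trend threshold in 1/year (default 0.013).
#' @param min_island_area_km2 resolution limit, for reporting (default 0.06).
#' @param min_valid_obs minimum cloud-free observations for a trend fit
#'   (default 10); guards against cloud-gap artifacts.
#' @export
detection_config <- function(shallow_threshold = 0.005,
                             shallow_min_count = 20L,
                             slope_threshold = 0.013,
                             min_island_area_km2 = 0.06,
                             min_valid_obs = 10L) {
  vals <- c(shallow_threshold, shallow_min_count, slope_threshold,
            min_island_area_km2, min_valid_obs)
  if (any(vals <= 0)) stop("all detection thresholds must be > 0")
  structure(list(shallow_threshold = shallow_threshold,
                 shallow_min_count = as.integer(shallow_min_count),
                 slope_threshold = slope_threshold,
                 min_island_area_km2 = min_island_area_km2,
                 min_valid_obs = as.integer(min_valid_obs)),
            class = "detection_config")
}

#' Map shallow water from red-band exceedance counts
#'
#' A pixel is shallow if its red-band (645 nm) reflectance exceeds
#' `cfg$shallow_threshold` in at least `cfg$shallow_min_count` cloud-free
#' passes within the window. The synthetic series exposes Rayleigh-corrected
#' reflectance in the red channel; this is used as a proxy for the
#' remote-sensing reflectance product the criterion was calibrated on.
#'
#' @param series a `scene_series`.
#' @param cfg a [detection_config()].
#' @param year_window a year (e.g. `2013`) or a vector of two `Date`s.
#' @return logical shallow-water mask.
#' @export
detect_shallow_water <- function(series, cfg = detection_config(),
                                 year_window = NULL) {
  dates <- series$dates
  if (is.null(year_window)) {
    sel <- rep(TRUE, length(dates))
  } else if (is.numeric(year_window) && length(year_window) == 1L) {
    sel <- as.integer(format(dates, "%Y")) == as.integer(year_window)
  } else {
    w <- as.Date(year_window)
    sel <- dates >= w[1L] & dates <= w[2L]
  }
  if (!any(sel)) stop("year_window lies outside the series dates")
  idx <- which(sel)
  count <- matrix(0L, series$grid$ny, series$grid$nx)
  for (t in idx) {
    exceed <- series$bands$rrc_645[, , t] > cfg$shallow_threshold &
      !series$cloud[, , t]
    count <- count + exceed
  }
  mask_on_grid(count >= cfg$shallow_min_count, series$grid)
}

#' Per-pixel temporal trend of a reflectance band
#'
#' Ordinary least squares (with intercept) of the band value against time in
#' fractional years since the first observation, using cloud-free
#' observations only. Pixels with fewer than `min_valid_obs` usable
#' observations carry `NA`.
#'
#' @param series a `scene_series`.
#' @param band band wavelength (default 859) or band name.
#' @param cloud optional `ny x nx x nt` logical array overriding the series'
#'   own cloud grids.
#' @param min_valid_obs minimum observations per pixel (default 2; island
#'   detection applies its own stricter guard).
#' @return a `slope_grid`: list with `slope` (1/year) and `n_obs` matrices.
#' @export
fit_temporal_slope <- function(series, band = 859L, cloud = NULL,
                               min_valid_obs = 2L) {
  bname <- if (is.character(band)) band else paste0("rrc_", band)
  arr <- series$bands[[bname]]
  if (is.null(arr)) stop("series lacks band ", bname)
  if (is.null(cloud)) cloud <- series$cloud
  nt <- length(series$dates)
  tt <- as.numeric(series$dates - series$dates[1L]) / 365.25
  ny <- series$grid$ny; nx <- series$grid$nx
  n <- matrix(0, ny, nx); st <- matrix(0, ny, nx); stt <- matrix(0, ny, nx)
  sy <- matrix(0, ny, nx); sty <- matrix(0, ny, nx)
  for (t in seq_len(nt)) {
    v <- !cloud[, , t]
    y <- arr[, , t]
    ok <- v & !is.na(y)
    y[!ok] <- 0
    n <- n + ok
    st <- st + tt[t] * ok
    stt <- stt + tt[t]^2 * ok
    sy <- sy + y
    sty <- sty + tt[t] * y
  }
  denom <- n * stt - st^2
  slope <- (n * sty - st * sy) / denom
  slope[n < max(2L, min_valid_obs) | abs(denom) < 1e-12] <- NA_real_
  structure(list(slope = slope, n_obs = n, grid = series$grid,
                 band = bname),
            class = "slope_grid")
}

#' Detect newly built islands from the NIR trend grid
#'
#' A pixel is flagged when its 859-nm slope exceeds `cfg$slope_threshold`
#' and it has at least `cfg$min_valid_obs` cloud-free observations.
#'
#' @param slopes a `slope_grid` from [fit_temporal_slope()].
#' @param cfg a [detection_config()].
#' @return logical island mask.
#' @export
detect_new_islands <- function(slopes, cfg = detection_config()) {
  m <- !is.na(slopes$slope) & slopes$slope > cfg$slope_threshold &
    slopes$n_obs >= cfg$min_valid_obs
  mask_on_grid(m, slopes$grid)
}

#' Summarise 8-connected components of a detection mask
#'
#' @param mask logical matrix with a grid attribute (or pass `grid`).
#' @param grid the mask's grid if not attached.
#' @return a `data.frame` with one row per component: `component`,
#'   `n_pixels`, `area_km2` (pixel count / 16) and centroid `lat`/`lon`.
#' @export
island_components <- function(mask, grid = NULL) {
  if (is.null(grid)) grid <- attr(mask, "grid")
  lab <- label_components(mask)
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) {
    return(data.frame(component = integer(), n_pixels = integer(),
                      area_km2 = numeric(), lat = numeric(), lon = numeric()))
  }
  lats <- if (!is.null(grid)) grid_lat(grid) else seq_len(nrow(mask))
  lons <- if (!is.null(grid)) grid_lon(grid) else seq_len(ncol(mask))
  rows <- do.call(rbind, lapply(ids, function(id) {
    idx <- which(lab == id)
    r <- (idx - 1L) %% nrow(mask) + 1L
    c <- (idx - 1L) %/% nrow(mask) + 1L
    data.frame(component = id, n_pixels = length(idx),
               area_km2 = length(idx) / 16,
               lat = mean(lats[r]), lon = mean(lons[c]))
  }))
  rownames(rows) <- NULL
  rows
}
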