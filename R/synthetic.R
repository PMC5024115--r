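# Synthetic multi-band scene generator. Produces MODIS-like time series of
# Rayleigh-corrected reflectance (bands 469, 555, 645, 859 nm) over a scene
# containing deep water, submerged reef, growing artificial islands,
# turbidity plumes, sunglint episodes and cloud fields, together with the
# ground truth of every injected layer. Every downstream stage of the
# pipeline is testable against this truth by parameter recovery.

BAND_NAMES <- c("rrc_469", "rrc_555", "rrc_645", "rrc_859")
BAND_WAVELENGTHS <- c(469L, 555L, 645L, 859L)

#' Default surface spectra for the synthetic generator
#'
#' Per-class mean Rayleigh-corrected reflectance at (469, 555, 645, 859) nm.
#' Deep water is dark with near-zero NIR; submerged reef adds benthic signal
#' to the green and red bands only (so its Turbidity Index, the 469 - 645
#' difference, is slightly negative); island/land is bright with high NIR and
#' strongly negative TI; cloud is bright in all bands. All values are
#' dimensionless reflectances.
#'
#' @return a named list of 4-vectors (`deep`, `reef_delta`, `land`, `cloud`).
#' @export
default_spectra <- function() {
  list(
    deep       = c(rrc_469 = 0.030, rrc_555 = 0.020, rrc_645 = 0.008, rrc_859 = 0.002),
    reef_delta = c(rrc_469 = 0.000, rrc_555 = 0.025, rrc_645 = 0.030, rrc_859 = 0.001),
    land       = c(rrc_469 = 0.10,  rrc_555 = 0.12,  rrc_645 = 0.15,  rrc_859 = 0.25),
    cloud      = c(rrc_469 = 0.60,  rrc_555 = 0.60,  rrc_645 = 0.60,  rrc_859 = 0.60)
  )
}

#' An island-building event
#'
#' Describes conversion of part of a reef to an artificial island. The final
#' footprint may be given as a polygon or as a target area around a centre
#' point (in which case the footprint is a compact blob of
#' `round(area_km2 * 16)` pixels grown outward from the centre). The growth
#' curve maps dates to the fraction of the final footprint present: 0 before
#' `start_date`, 1 at and after `end_date`, non-decreasing in between
#' (default linear). Footprint pixels are ranked by distance from the growth
#' origin so the island mask is non-decreasing in time.
#'
#' @param reef_id name of the reef being built on.
#' @param start_date,end_date `Date`s bounding construction.
#' @param footprint_polygon final outline (anything [as_polygon()] accepts),
#'   or `NULL` to use `center`/`area_km2`.
#' @param center `c(lon, lat)` used when growing a blob footprint and as the
#'   growth origin.
#' @param area_km2 target final area when no polygon is given.
#' @param growth_curve optional `function(dates) -> fraction in [0,1]`.
#' @export
island_event <- function(reef_id, start_date, end_date,
                         footprint_polygon = NULL, center = NULL,
                         area_km2 = NULL, growth_curve = NULL) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("island_event: end_date before start_date")
  if (is.null(footprint_polygon) && (is.null(center) || is.null(area_km2)))
    stop("island_event: give footprint_polygon, or center + area_km2")
  structure(list(reef_id = reef_id, start_date = start_date,
                 end_date = end_date,
                 footprint_polygon = if (!is.null(footprint_polygon))
                   as_polygon(footprint_polygon) else NULL,
                 center = center, area_km2 = area_km2,
                 growth_curve = growth_curve),
            class = "island_event")
}

#' A turbidity-plume event on a single date
#'
#' The plume raises the blue band relative to the red band so its Turbidity
#' Index (469 - 645 difference) exceeds that of the surrounding clear water
#' by `0.7 * ti_amplitude` (the spectral perturbation is
#' `+amp, +0.6 amp, +0.3 amp, +0.05 amp` across the four bands). The
#' footprint is a polygon or a circular blob with an optional drift offset.
#'
#' @param reef_id source reef name.
#' @param date `Date` of the plume.
#' @param polygon explicit footprint, or `NULL` to use the blob parameters.
#' @param center `c(lon, lat)` blob centre (before drift).
#' @param radius_km blob radius.
#' @param drift_km `c(east, north)` displacement in km applied to the centre.
#' @param ti_amplitude dimensionless reflectance offset (default 0.05).
#' @export
plume_event <- function(reef_id, date, polygon = NULL, center = NULL,
                        radius_km = NULL, drift_km = c(0, 0),
                        ti_amplitude = 0.05) {
  if (ti_amplitude <= 0) stop("plume_event: ti_amplitude must be > 0")
  if (is.null(polygon) && (is.null(center) || is.null(radius_km)))
    stop("plume_event: give polygon, or center + radius_km")
  structure(list(reef_id = reef_id, date = as.Date(date),
                 polygon = if (!is.null(polygon)) as_polygon(polygon) else NULL,
                 center = center, radius_km = radius_km,
                 drift_km = drift_km, ti_amplitude = ti_amplitude),
            class = "plume_event")
}

#' A sunglint episode on a single date
#'
#' Glint is additive: observed band = glint-free band + shape(lambda) * g,
#' where g >= 0 is the per-pixel glint magnitude and the spectral shape has
#' its 859-nm multiplier fixed to 1. The default shape (0.67, 0.80, 0.94, 1)
#' matches the deglinting coefficients, so over zero-NIR water the correction
#' cancels injected glint exactly. The default spatial field is `magnitude`
#' times a smooth west-to-east gradient from 0.5 to 1.5.
#'
#' @param date `Date` of the episode.
#' @param magnitude overall glint reflectance scale (>= 0).
#' @param shape per-band multipliers, 859 nm entry must be 1.
#' @param field_fun optional `function(grid) -> ny x nx matrix >= 0`.
#' @export
glint_event <- function(date, magnitude,
                        shape = c(0.67, 0.80, 0.94, 1.0),
                        field_fun = NULL) {
  if (magnitude < 0) stop("glint_event: magnitude must be >= 0")
  if (length(shape) != 4L) stop("glint_event: shape must have 4 entries")
  if (shape[4L] != 1) stop("glint_event: the 859-nm shape multiplier is fixed to 1")
  structure(list(date = as.Date(date), magnitude = magnitude,
                 shape = shape, field_fun = field_fun),
            class = "glint_event")
}

#' Cloud-field model
#'
#' Each scene receives a cloud mask built from smoothed random noise
#' thresholded at the (1 - coverage) quantile, giving blobs with the stated
#' coverage fraction. Cloudy pixels are overwritten with the bright cloud
#' spectrum in all bands.
#'
#' @param coverage fraction of pixels cloudy per scene (default 0.3).
#' @param scale_px blob length scale in pixels (default 8).
#' @export
cloud_model <- function(coverage = 0.3, scale_px = 8L) {
  if (coverage < 0 || coverage > 1) stop("cloud_model: coverage must be in [0, 1]")
  structure(list(coverage = coverage, scale_px = as.integer(scale_px)),
            class = "cloud_model")
}

#' Configuration of a synthetic scene series
#'
#' @param grid a [scene_grid()].
#' @param start_date,end_date date range of the series.
#' @param revisit days between passes (default 1).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @param spectra per-class spectra as from [default_spectra()].
#' @param reefs named list of reef outline polygons (static shallow areas).
#' @param islands list of [island_event()]s.
#' @param plumes list of [plume_event()]s.
#' @param glints list of [glint_event()]s.
#' @param clouds a [cloud_model()] or `NULL` for cloud-free skies.
#' @param noise_sd per-pixel Gaussian noise sd applied after compositing,
#'   before the cloud overwrite (default 0.002).
#' @export
scene_config <- function(grid, start_date, end_date, revisit = 1L, seed = 1L,
                         spectra = default_spectra(), reefs = list(),
                         islands = list(), plumes = list(), glints = list(),
                         clouds = NULL, noise_sd = 0.002) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("scene_config: empty date range")
  if (revisit < 1) stop("scene_config: revisit must be >= 1 day")
  for (cls in c("deep", "land", "cloud")) {
    v <- spectra[[cls]]
    if (any(v < 0) || any(v > 1.5))
      stop("scene_config: ", cls, " reflectance means must lie in [0, 1.5]")
  }
  if (noise_sd < 0) stop("scene_config: noise_sd must be >= 0")
  dates <- seq(start_date, end_date, by = as.integer(revisit))
  cfg <- structure(list(grid = grid, dates = dates, seed = as.integer(seed),
                        spectra = spectra, reefs = reefs, islands = islands,
                        plumes = plumes, glints = glints, clouds = clouds,
                        noise_sd = noise_sd),
                   class = "scene_config")
  validate_events(cfg)
  cfg
}

validate_events <- function(cfg) {
  rng <- range(cfg$dates)
  for (ev in cfg$islands) {
    if (ev$start_date < rng[1L] || ev$end_date > rng[2L])
      stop("island_event '", ev$reef_id, "' dates outside the series date_range")
  }
  for (ev in cfg$plumes) {
    if (ev$date < rng[1L] || ev$date > rng[2L])
      stop("plume_event '", ev$reef_id, "' date outside the series date_range")
  }
  for (ev in cfg$glints) {
    if (ev$date < rng[1L] || ev$date > rng[2L])
      stop("glint_event date outside the series date_range")
  }
  invisible(cfg)
}

# Final footprint mask of an island event, plus the order in which pixels
# appear during growth (rank by distance from the growth origin).
island_footprint <- function(ev, grid) {
  if (!is.null(ev$footprint_polygon)) {
    mask <- rasterize_polygon(ev$footprint_polygon, grid)
    if (is.null(ev$center)) {
      idx <- which(mask)
      rows <- (idx - 1L) %% grid$ny + 1L
      cols <- (idx - 1L) %/% grid$ny + 1L
      origin <- c(mean(grid_lon(grid)[cols]), mean(grid_lat(grid)[rows]))
    } else origin <- ev$center
  } else {
    n_target <- max(1L, as.integer(round(ev$area_km2 * 16)))
    mask <- blob_mask(grid, ev$center, n_target)
    origin <- ev$center
  }
  idx <- which(mask)
  if (!length(idx)) stop("island_event '", ev$reef_id, "' has an empty footprint")
  rows <- (idx - 1L) %% grid$ny + 1L
  cols <- (idx - 1L) %/% grid$ny + 1L
  d2 <- (grid_lon(grid)[cols] - origin[1L])^2 + (grid_lat(grid)[rows] - origin[2L])^2
  list(mask = mask, order = idx[order(d2, idx)])
}

# Compact blob of exactly n pixels nearest to a centre point.
blob_mask <- function(grid, center, n) {
  lons <- grid_lon(grid); lats <- grid_lat(grid)
  d2 <- outer(lats - center[2L], lons - center[1L],
              function(a, b) a^2 + b^2)
  ord <- order(d2)[seq_len(min(n, length(d2)))]
  m <- empty_mask(grid)
  m[ord] <- TRUE
  m
}

growth_fraction <- function(ev, date) {
  if (!is.null(ev$growth_curve)) {
    f <- ev$growth_curve(date)
    if (f < -1e-9 || f > 1 + 1e-9) stop("growth_curve outside [0, 1]")
    return(min(max(f, 0), 1))
  }
  if (date < ev$start_date) return(0)
  if (date >= ev$end_date) return(1)
  span <- as.numeric(ev$end_date - ev$start_date)
  as.numeric(date - ev$start_date) / span
}

plume_footprint <- function(ev, grid) {
  if (!is.null(ev$polygon)) return(rasterize_polygon(ev$polygon, grid))
  ctr <- c(ev$center[1L] + ev$drift_km[1L] / 111.32,
           ev$center[2L] + ev$drift_km[2L] / 111.32)
  rasterize_polygon(circle_polygon(ctr[1L], ctr[2L], ev$radius_km), grid)
}

glint_field <- function(ev, grid) {
  if (!is.null(ev$field_fun)) {
    g <- ev$field_fun(grid)
    if (any(g < 0)) stop("glint field must be >= 0")
    return(g * ev$magnitude)
  }
  grad <- matrix(rep(seq(0.5, 1.5, length.out = grid$nx), each = grid$ny),
                 grid$ny, grid$nx)
  ev$magnitude * grad
}

# Smoothed-noise cloud field: coarse Gaussian noise, block-upsampled,
# box-smoothed, thresholded at the (1 - coverage) quantile.
cloud_field <- function(model, grid) {
  if (model$coverage <= 0) return(matrix(FALSE, grid$ny, grid$nx))
  if (model$coverage >= 1) return(matrix(TRUE, grid$ny, grid$nx))
  s <- max(1L, model$scale_px)
  cy <- ceiling(grid$ny / s) + 1L
  cx <- ceiling(grid$nx / s) + 1L
  coarse <- matrix(stats::rnorm(cy * cx), cy, cx)
  up <- coarse[rep(seq_len(cy), each = s), rep(seq_len(cx), each = s)]
  up <- up[seq_len(grid$ny), seq_len(grid$nx), drop = FALSE]
  sm <- box_smooth(box_smooth(up))
  thr <- stats::quantile(sm, 1 - model$coverage, names = FALSE)
  sm > thr
}

box_smooth <- function(m) {
  # 3x3 mean with edge replication
  ny <- nrow(m); nx <- ncol(m)
  pad <- m[c(1L, seq_len(ny), ny), c(1L, seq_len(nx), nx)]
  acc <- matrix(0, ny, nx)
  for (dy in 0:2) for (dx in 0:2) {
    acc <- acc + pad[dy + seq_len(ny), dx + seq_len(nx)]
  }
  acc / 9
}

#' Generate a synthetic scene series with ground truth
#'
#' Composites each scene in the order baseline -> island growth -> plume ->
#' glint, adds per-pixel Gaussian noise, then overwrites cloudy pixels with
#' the cloud spectrum. The truth records island, plume, cloud and glint
#' layers before cloud occlusion, along with the static reef mask and
#' per-date plume areas.
#'
#' @param config a [scene_config()].
#' @return a list with elements `series` (a `scene_series`: grid, dates,
#'   per-band `ny x nx x nt` arrays, cloud array, solar zenith angles) and
#'   `truth` (a `synthetic_truth`: island/plume/cloud logical arrays, glint
#'   magnitude array, reef mask, per-date plume area in km^2, per-island
#'   final footprints).
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  grid <- config$grid
  ny <- grid$ny; nx <- grid$nx
  dates <- config$dates
  nt <- length(dates)
  sp <- config$spectra

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  # static layers
  reef_mask <- empty_mask(grid)
  for (p in config$reefs) reef_mask <- reef_mask | rasterize_polygon(p, grid)

  footprints <- lapply(config$islands, island_footprint, grid = grid)
  if (length(footprints) > 1L) {
    tot <- Reduce(`+`, lapply(footprints, function(f) f$mask + 0L))
    if (any(tot > 1L))
      stop("overlapping island footprints across distinct reef_ids")
  }

  # per-date event lookup
  plume_by_date <- split(seq_along(config$plumes),
                         as.character(vapply(config$plumes,
                                             function(e) as.character(e$date), "")))
  glint_by_date <- split(seq_along(config$glints),
                         as.character(vapply(config$glints,
                                             function(e) as.character(e$date), "")))
  plume_fps <- lapply(config$plumes, plume_footprint, grid = grid)
  glint_fields <- lapply(config$glints, glint_field, grid = grid)

  base <- lapply(BAND_NAMES, function(b) {
    m <- matrix(sp$deep[[b]], ny, nx)
    m[reef_mask] <- sp$deep[[b]] + sp$reef_delta[[b]]
    m
  })
  names(base) <- BAND_NAMES

  bands <- lapply(BAND_NAMES, function(b) array(NA_real_, c(ny, nx, nt)))
  names(bands) <- BAND_NAMES
  cloud_arr <- array(FALSE, c(ny, nx, nt))
  island_arr <- array(FALSE, c(ny, nx, nt))
  plume_arr <- array(FALSE, c(ny, nx, nt))
  glint_arr <- array(0, c(ny, nx, nt))
  plume_area <- numeric(nt)

  doy <- as.integer(format(dates, "%j"))
  solar_zenith <- 25 + 10 * abs(sin(2 * pi * doy / 365.25))
  # plume spectral perturbation per unit ti_amplitude
  plume_shape <- c(rrc_469 = 1.0, rrc_555 = 0.6, rrc_645 = 0.3, rrc_859 = 0.05)

  for (t in seq_len(nt)) {
    d <- dates[t]
    sl <- lapply(base, identity)

    # island growth
    isl <- matrix(FALSE, ny, nx)
    for (k in seq_along(footprints)) {
      f <- growth_fraction(config$islands[[k]], d)
      npix <- as.integer(round(f * length(footprints[[k]]$order)))
      if (npix > 0L) isl[footprints[[k]]$order[seq_len(npix)]] <- TRUE
    }
    if (any(isl)) {
      for (b in BAND_NAMES) sl[[b]][isl] <- sp$land[[b]]
    }
    island_arr[, , t] <- isl

    # plumes (in-water only; never over island pixels)
    pk <- plume_by_date[[as.character(d)]]
    if (!is.null(pk)) {
      pm <- matrix(FALSE, ny, nx)
      for (k in pk) pm <- pm | plume_fps[[k]]
      pm <- pm & !isl
      for (k in pk) {
        fp <- plume_fps[[k]] & !isl
        amp <- config$plumes[[k]]$ti_amplitude
        for (b in BAND_NAMES) {
          sl[[b]][fp] <- sl[[b]][fp] + plume_shape[[b]] * amp
        }
      }
      plume_arr[, , t] <- pm
      plume_area[t] <- sum(pm) / 16
    }

    # glint (additive, spectral shape applied to the magnitude field)
    gk <- glint_by_date[[as.character(d)]]
    if (!is.null(gk)) {
      g <- matrix(0, ny, nx)
      for (k in gk) g <- g + glint_fields[[k]]
      shp <- config$glints[[gk[1L]]]$shape
      for (i in seq_along(BAND_NAMES)) {
        sl[[BAND_NAMES[i]]] <- sl[[BAND_NAMES[i]]] + shp[i] * g
      }
      glint_arr[, , t] <- g
    }

    # noise after compositing, before the cloud overwrite
    if (config$noise_sd > 0) {
      for (b in BAND_NAMES) {
        sl[[b]] <- sl[[b]] + matrix(stats::rnorm(ny * nx, 0, config$noise_sd), ny, nx)
      }
    }

    # clouds overwrite everything; truth keeps the occluded layers
    if (!is.null(config$clouds)) {
      cm <- cloud_field(config$clouds, grid)
      if (any(cm)) {
        for (b in BAND_NAMES) sl[[b]][cm] <- sp$cloud[[b]]
      }
      cloud_arr[, , t] <- cm
    }

    for (b in BAND_NAMES) bands[[b]][, , t] <- sl[[b]]
  }

  series <- structure(list(grid = grid, dates = dates, bands = bands,
                           cloud = cloud_arr, solar_zenith = solar_zenith),
                      class = "scene_series")
  final_islands <- lapply(footprints, function(f) f$mask)
  names(final_islands) <- vapply(config$islands, function(e) e$reef_id, "")
  truth <- structure(list(grid = grid, dates = dates, island = island_arr,
                          plume = plume_arr, cloud = cloud_arr,
                          glint = glint_arr, reef_mask = reef_mask,
                          plume_area_km2 = plume_area,
                          island_footprints = final_islands),
                     class = "synthetic_truth")
  list(series = series, truth = truth)
}

#' @export
print.scene_series <- function(x, ...) {
  cat(sprintf("<scene_series> %d scenes of %d x %d pixels, %s to %s\n",
              length(x$dates), x$grid$ny, x$grid$nx,
              format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

#' Extract one scene observation from a series
#'
#' @param series a `scene_series`.
#' @param i time index or a `Date`.
#' @return a `scene_observation`: per-band matrices plus `cloud`, `date`,
#'   `solar_zenith` and the grid.
#' @export
scene_at <- function(series, i) {
  if (inherits(i, "Date")) {
    i <- match(i, series$dates)
    if (is.na(i)) stop("date not present in series")
  }
  obs <- lapply(series$bands, function(a) a[, , i])
  obs$cloud <- series$cloud[, , i]
  obs$date <- series$dates[i]
  obs$solar_zenith <- series$solar_zenith[i]
  obs$grid <- series$grid
  structure(obs, class = "scene_observation")
}
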