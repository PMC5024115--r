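# Turbidity-plume quantification: delineations (manual polygons or the
# automated surrogate), areas by the 1/16 km^2 pixel rule, time series,
# spatial frequency maps, and the affected-once fraction.

#' A dated plume delineation
#'
#' Rasterizes delineation polygons by pixel-centre containment and removes
#' cloud-masked pixels, so the footprint never intersects the cloudmask and
#' `area_km2` is exactly the footprint pixel count / 16.
#'
#' @param reef_id reef the plume is attributed to.
#' @param date `Date` of the scene.
#' @param polygons delineation polygons ([as_polygon()] input or a list of
#'   them), or `NULL` when passing `footprint` directly.
#' @param grid the [scene_grid()].
#' @param cloud optional logical cloudmask excluded from the footprint.
#' @param footprint a ready-made logical mask (alternative to `polygons`).
#' @param source `"manual"` or `"auto"`; automated surrogate delineations
#'   are always labelled and never merged silently with manual ones.
#' @export
plume_delineation <- function(reef_id, date, polygons = NULL, grid = NULL,
                              cloud = NULL, footprint = NULL,
                              source = "manual") {
  if (is.null(footprint)) {
    if (is.null(grid)) stop("give `grid` to rasterize polygons")
    footprint <- empty_mask(grid)
    if (!is.null(polygons)) {
      if (is.matrix(polygons) || inherits(polygons, "reef_polygon"))
        polygons <- list(polygons)
      for (p in polygons) footprint <- footprint | rasterize_polygon(p, grid)
    }
  } else if (!is.null(grid)) {
    footprint <- mask_on_grid(footprint, grid)
  }
  if (!is.null(cloud)) footprint <- footprint & !cloud
  structure(list(reef_id = reef_id, date = as.Date(date),
                 footprint = footprint,
                 area_km2 = sum(footprint) / 16,
                 source = source),
            class = "plume_delineation")
}

#' @export
print.plume_delineation <- function(x, ...) {
  cat(sprintf("<plume_delineation> %s %s: %.4f km^2 (%s)\n",
              x$reef_id, format(x$date), x$area_km2, x$source))
  invisible(x)
}

#' Plume areal extent in km^2
#'
#' Footprint pixel count multiplied by 1/16.
#'
#' @param d a [plume_delineation()].
#' @export
plume_area <- function(d) {
  stopifnot(inherits(d, "plume_delineation"))
  sum(d$footprint) / 16
}

#' Automated plume delineation surrogate
#'
#' Replaces manual on-screen delineation for synthetic testing: pixels whose
#' Turbidity Index exceeds a threshold (default: median TI of clear deep
#' water plus `k` times its MAD), not cloud-masked, restricted to the
#' 8-connected components that touch a dilated buffer around the reef mask
#' (plumes emanate from the construction site). The result is labelled
#' `source = "auto"`.
#'
#' @param ti TI matrix (NA where cloudy is acceptable).
#' @param reef_mask logical mask of the source reef(s).
#' @param cloud logical cloudmask.
#' @param reef_id,date passed to the delineation.
#' @param ti_threshold explicit threshold; `NULL` for median + k * MAD.
#' @param k robust multiplier for the automatic threshold (default 5).
#' @param buffer_px reef buffer radius in pixels (default 4).
#' @param grid the scene grid.
#' @return a [plume_delineation()]; empty with attribute
#'   `fully_clouded = TRUE` when no clear pixel exists.
#' @export
auto_delineate <- function(ti, reef_mask, cloud, reef_id, date, grid,
                           ti_threshold = NULL, k = 5, buffer_px = 4L) {
  clear <- !cloud & !is.na(ti)
  if (!any(clear)) {
    d <- plume_delineation(reef_id, date, grid = grid, source = "auto")
    attr(d, "fully_clouded") <- TRUE
    return(d)
  }
  if (is.null(ti_threshold)) {
    ref <- ti[clear & !reef_mask]
    if (!length(ref)) ref <- ti[clear]
    ti_threshold <- stats::median(ref) + k * stats::mad(ref)
  }
  cand <- !is.na(ti) & ti > ti_threshold & !cloud
  if (any(cand)) {
    lab <- label_components(cand)
    buf <- dilate_mask_px(reef_mask, as.integer(buffer_px))
    keep <- unique(lab[lab > 0L & buf])
    cand <- lab > 0L & matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  plume_delineation(reef_id, date, grid = grid, cloud = cloud,
                    footprint = cand, source = "auto")
}

#' Tabulate plume areas over time
#'
#' One row per (reef, date); delineations with empty footprints record an
#' examined-but-absent plume as 0 km^2. Duplicate (reef, date) pairs are an
#' error.
#'
#' @param ds list of [plume_delineation()]s.
#' @return a `data.table` with columns `reef_id`, `date`, `area_km2`.
#' @export
plume_time_series <- function(ds) {
  if (!length(ds)) {
    return(data.table::data.table(reef_id = character(),
                                  date = as.Date(character()),
                                  area_km2 = numeric()))
  }
  dt <- data.table::data.table(
    reef_id = vapply(ds, function(d) d$reef_id, ""),
    date = as.Date(vapply(ds, function(d) as.character(d$date), "")),
    area_km2 = vapply(ds, plume_area, numeric(1))
  )
  if (anyDuplicated(dt, by = c("reef_id", "date")))
    stop("duplicate (reef_id, date) delineations")
  data.table::setkeyv(dt, c("reef_id", "date"))
  dt[]
}

coverage_count <- function(ds) {
  if (!length(ds)) stop("no delineations")
  acc <- ds[[1L]]$footprint + 0L
  for (d in ds[-1L]) acc <- acc + d$footprint
  acc
}

#' Spatial frequency of plume coverage
#'
#' Per pixel, `100 * (number of delineations containing the pixel) /
#' n_total_images`. Whether `n_total_images` counts all examined images or
#' only those with plumes is the caller's choice.
#'
#' @param ds list of [plume_delineation()]s.
#' @param n_total_images denominator; must be >= the number of distinct
#'   delineation dates and > 0.
#' @return numeric matrix of percentages in `[0, 100]`.
#' @export
plume_frequency_map <- function(ds, n_total_images) {
  if (n_total_images <= 0) stop("n_total_images must be > 0")
  ndates <- length(unique(vapply(ds, function(d) as.character(d$date), "")))
  if (n_total_images < ndates)
    stop("n_total_images is smaller than the number of delineation dates")
  if (!length(ds)) stop("no delineations")
  100 * coverage_count(ds) / n_total_images
}

#' Fraction of the affected area impacted exactly once
#'
#' (pixels covered by exactly one delineation) / (pixels covered at least
#' once). Errors when nothing is covered.
#'
#' @param ds list of [plume_delineation()]s.
#' @export
single_hit_fraction <- function(ds) {
  cc <- coverage_count(ds)
  n_any <- sum(cc >= 1L)
  if (n_any == 0L) stop("no pixel is covered by any delineation")
  sum(cc == 1L) / n_any
}

#' Union ("affected area") extent of a set of delineations, in km^2
#'
#' The per-reef spatial extent of delineated plumes: the union of all
#' footprints, pixel count / 16. Per-date areas double-count overlaps; the
#' union does not.
#'
#' @param ds list of [plume_delineation()]s.
#' @export
plume_union_area <- function(ds) {
  if (!length(ds)) return(0)
  sum(coverage_count(ds) >= 1L) / 16
}
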