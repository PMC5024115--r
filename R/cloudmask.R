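# Cloudmask post-processing: threshold probability grids, dilate the raw
# mask, and apply manual override polygons where the operational mask fails
# (bright island pixels flagged as cloud in obvious absence of clouds, or
# missed cloud edges).

#' Build the final dilated cloudmask
#'
#' A raw cloud grid (boolean, or a probability grid thresholded at
#' `prob_threshold`) is dilated by `radius_m` with a Euclidean disk, the
#' standard guard against undetected cloud edges.
#'
#' @param raw logical matrix, or numeric probability matrix in `[0, 1]`.
#' @param radius_m dilation radius in metres (default 500).
#' @param pixel_m pixel size in metres (default 250).
#' @param prob_threshold threshold applied when `raw` is numeric
#'   (default 0.5).
#' @return logical matrix containing the (thresholded) input.
#' @export
dilate_cloudmask <- function(raw, radius_m = 500, pixel_m = 250,
                             prob_threshold = 0.5) {
  if (is.numeric(raw) && !is.logical(raw)) {
    raw <- raw > prob_threshold
  }
  dilate_mask(raw, radius_m = radius_m, pixel_m = pixel_m)
}

#' A manual cloudmask override
#'
#' @param polygon anything [as_polygon()] accepts.
#' @param mode `"force_clear"` (unset pixels) or `"force_cloud"` (set
#'   pixels); the two modes are mutually exclusive per polygon.
#' @param date_start,date_end optional applicability window (inclusive);
#'   `NULL` means unbounded.
#' @export
mask_override <- function(polygon, mode = c("force_clear", "force_cloud"),
                          date_start = NULL, date_end = NULL) {
  mode <- match.arg(mode)
  structure(list(polygon = as_polygon(polygon), mode = mode,
                 date_start = if (!is.null(date_start)) as.Date(date_start),
                 date_end = if (!is.null(date_end)) as.Date(date_end)),
            class = "mask_override")
}

override_applies <- function(ov, date) {
  if (is.null(date)) return(TRUE)
  (is.null(ov$date_start) || date >= ov$date_start) &&
    (is.null(ov$date_end) || date <= ov$date_end)
}

#' Apply manual overrides to a cloudmask
#'
#' All applicable force_clear polygons are applied first (unsetting pixels),
#' then all force_cloud polygons (setting pixels); force_cloud therefore wins
#' where contradictory overrides overlap, and a warning reports the conflict.
#'
#' @param mask logical cloudmask on a [scene_grid()] (grid taken from the
#'   mask attribute or passed explicitly).
#' @param overrides list of [mask_override()]s.
#' @param date the scene date, used to filter overrides by applicability.
#' @param grid the mask's grid if not attached as an attribute.
#' @return the overridden logical mask.
#' @export
apply_overrides <- function(mask, overrides, date = NULL, grid = NULL) {
  if (is.null(grid)) grid <- attr(mask, "grid")
  if (is.null(grid)) stop("mask carries no grid; pass `grid`")
  active <- Filter(function(ov) override_applies(ov, date), overrides)
  if (!length(active)) return(mask)
  clear <- matrix(FALSE, grid$ny, grid$nx)
  cloudy <- matrix(FALSE, grid$ny, grid$nx)
  for (ov in active) {
    r <- rasterize_polygon(ov$polygon, grid)
    if (ov$mode == "force_clear") clear <- clear | r else cloudy <- cloudy | r
  }
  conflict <- clear & cloudy
  if (any(conflict))
    warning(sum(conflict), " pixel(s) under contradictory overrides; force_cloud wins")
  mask[clear] <- FALSE
  mask[cloudy] <- TRUE
  mask
}
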