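# Accounting of island-building projects: record parsing (including
# censored "<0.01" areas and Pre-OLI/Ongoing date sentinels), per-country
# totals, and per-reef campaign reports.

VALID_COUNTRIES <- c("C", "V", "T")

parse_area_field <- function(x, row, field) {
  x <- trimws(x)
  if (grepl("^<", x)) {
    hi <- suppressWarnings(as.numeric(sub("^<", "", x)))
    if (is.na(hi)) stop("row ", row, ": malformed ", field, " '", x, "'")
    return(list(value = NA_real_, upper = hi, censored = TRUE))
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("row ", row, ": malformed ", field, " '", x, "'")
  list(value = v, upper = v, censored = FALSE)
}

parse_monthyear <- function(x, row, field) {
  x <- trimws(x)
  if (x %in% c("Pre-OLI", "Ongoing")) {
    return(list(date = as.Date(NA), sentinel = x))
  }
  d <- as.Date(paste("01", x), tryFormats = c("%d %b %Y", "%d %B %Y"),
               optional = TRUE)
  if (is.na(d)) stop("row ", row, ": malformed ", field, " '", x, "'")
  list(date = d, sentinel = NA_character_)
}

#' Load island-building records from CSV
#'
#' Expects columns `reef_name, country, lat, lon, reef_area_km2,
#' island_area_km2, new_area_km2, start, end`. Censored areas written
#' `"<0.01"` are stored as an interval (0, 0.01): `new_area_km2` is `NA`,
#' `new_area_upper_km2` holds the bound and `new_area_censored` is TRUE.
#' Dates are month-year strings; `Pre-OLI` and `Ongoing` are first-class
#' sentinel values kept in `start_sentinel`/`end_sentinel`. Each record
#' must satisfy 0 <= new area <= island area (island vs reef area is not
#' asserted: reef outlines can be unreliable).
#'
#' @param path CSV file path.
#' @return a `data.table` of validated records (class `island_records`).
#' @export
load_island_records <- function(path) {
  raw <- data.table::fread(path, colClasses = "character")
  need <- c("reef_name", "country", "lat", "lon", "reef_area_km2",
            "island_area_km2", "new_area_km2", "start", "end")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(raw)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- raw[i]
    if (!nzchar(r$reef_name)) stop("row ", i, ": empty reef_name")
    if (!(r$country %in% VALID_COUNTRIES))
      stop("row ", i, ": unknown country code '", r$country, "'")
    num <- function(field) {
      v <- suppressWarnings(as.numeric(r[[field]]))
      if (is.na(v)) stop("row ", i, ": malformed ", field, " '", r[[field]], "'")
      v
    }
    island <- parse_area_field(r$island_area_km2, i, "island_area_km2")
    newa <- parse_area_field(r$new_area_km2, i, "new_area_km2")
    if (!newa$censored && !island$censored &&
        (newa$value < 0 || newa$value > island$value + 1e-9))
      stop("row ", i, ": new_area_km2 must lie in [0, island_area_km2]")
    st <- parse_monthyear(r$start, i, "start")
    en <- parse_monthyear(r$end, i, "end")
    out[[i]] <- data.table::data.table(
      reef_name = r$reef_name, country = r$country,
      lat = num("lat"), lon = num("lon"),
      reef_area_km2 = num("reef_area_km2"),
      island_area_km2 = island$value,
      new_area_km2 = newa$value,
      new_area_upper_km2 = newa$upper,
      new_area_censored = newa$censored,
      start_date = st$date, start_sentinel = st$sentinel,
      end_date = en$date, end_sentinel = en$sentinel
    )
  }
  rec <- data.table::rbindlist(out)
  data.table::setattr(rec, "class", c("island_records", class(rec)))
  rec[]
}

#' Path to the packaged island-building summary table
#'
#' A verbatim CSV transcription of the published project summary (15
#' records: seven Chinese, seven Vietnamese and one Taiwanese project).
#' @export
island_records_fixture <- function() {
  system.file("extdata", "table1_islands.csv", package = "reefwatch",
              mustWork = TRUE)
}

#' Published per-country totals of new island area
#'
#' The printed per-country totals (China 14.52, Vietnam 0.54, Taiwan
#' 0.06 km^2). The Vietnam column sum is not recoverable from the rounded
#' per-project entries (two are censored "<0.01"), so the printed totals
#' ship as their own fixture.
#'
#' @return a `data.table` with `country`, `total_new_area_km2`.
#' @export
printed_country_totals <- function() {
  data.table::fread(system.file("extdata", "table1_country_totals.csv",
                                package = "reefwatch", mustWork = TRUE))
}

#' Published per-reef plume extents and image counts
#'
#' Spatial extents of delineated plumes (union of footprints over the
#' campaign) and the number of images examined / with plumes, per reef, as
#' printed.
#'
#' @return a `data.table` with `reef_id`, `images_examined`,
#'   `images_with_plumes`, `extent_km2`.
#' @export
printed_plume_extents <- function() {
  data.table::fread(system.file("extdata", "plume_extents.csv",
                                package = "reefwatch", mustWork = TRUE))
}

#' Per-country totals of new island area
#'
#' Sums `new_area_km2` by country over non-censored records; censored
#' entries ("<0.01") are excluded from the exact sum and counted in
#' `n_censored` (the sum is therefore a lower bound where `n_censored > 0`).
#' Display values are rounded to 2 decimals; the unrounded sum is retained.
#'
#' @param records an `island_records` table.
#' @return a `data.table` with `country`, `total_new_area_km2` (unrounded),
#'   `total_display` (2 dp), `n_projects`, `n_censored`.
#' @export
country_totals <- function(records) {
  if (nrow(records) == 0L) {
    return(data.table::data.table(country = character(),
                                  total_new_area_km2 = numeric(),
                                  total_display = numeric(),
                                  n_projects = integer(),
                                  n_censored = integer()))
  }
  bad <- setdiff(unique(records$country), VALID_COUNTRIES)
  if (length(bad)) stop("unknown country code(s): ", paste(bad, collapse = ", "))
  new_area_km2 <- new_area_censored <- country <- NULL  # NSE bindings
  tot <- records[, list(
    total_new_area_km2 = sum(new_area_km2[!new_area_censored]),
    n_projects = .N,
    n_censored = sum(new_area_censored)
  ), by = country]
  tot$total_display <- round(tot$total_new_area_km2, 2)
  data.table::setcolorder(tot, c("country", "total_new_area_km2",
                                 "total_display", "n_projects", "n_censored"))
  tot[]
}

#' Flag records outside a grid's bounds
#'
#' Records are never silently dropped; those outside the configured grid are
#' flagged so reports can annotate them.
#'
#' @param records an `island_records` table.
#' @param grid a [scene_grid()].
#' @return the records with a logical `in_grid` column added.
#' @export
flag_outside_grid <- function(records, grid) {
  records <- data.table::copy(records)
  records$in_grid <- records$lat >= grid$lat_min & records$lat <= grid$lat_max &
    records$lon >= grid$lon_min & records$lon <= grid$lon_max
  records[]
}

#' Per-reef campaign report
#'
#' Bundles, for each reef with an island-area trajectory: the trajectory,
#' the plume-area time series, and summary totals (final island area, union
#' plume extent, single-hit fraction where defined), plus one combined
#' totals table. Reef ids appearing in `plumes` but not in the trajectories
#' or records are an error.
#'
#' @param island_areas `data.table` with `reef_id`, `date`, `area_km2`
#'   (detected or truth island-area trajectory).
#' @param records optional `island_records` table (matched on `reef_name`).
#' @param plumes optional list of [plume_delineation()]s.
#' @return a `campaign_report`: list with `reports` (per reef) and
#'   `combined` (totals table).
#' @export
campaign_report <- function(island_areas, records = NULL, plumes = list()) {
  island_areas <- data.table::as.data.table(island_areas)
  reef_ids <- unique(island_areas$reef_id)
  plume_ids <- unique(vapply(plumes, function(d) d$reef_id, ""))
  known <- union(reef_ids, if (!is.null(records)) records$reef_name else character())
  unknown <- setdiff(plume_ids, known)
  if (length(unknown))
    stop("plume delineations reference unknown reef id(s): ",
         paste(unknown, collapse = ", "))
  reports <- lapply(reef_ids, function(id) {
    reef_id <- NULL
    traj <- island_areas[reef_id == id][order(date)]
    pls <- Filter(function(d) d$reef_id == id, plumes)
    ts <- plume_time_series(pls)
    list(
      reef_id = id,
      island_trajectory = traj,
      final_island_area_km2 = if (nrow(traj)) traj$area_km2[nrow(traj)] else NA_real_,
      plume_series = ts,
      plume_union_km2 = plume_union_area(pls),
      single_hit_fraction = if (length(pls) && any(vapply(pls, function(d)
        any(d$footprint), NA))) single_hit_fraction(pls) else NA_real_,
      record = if (!is.null(records)) records[records$reef_name == id] else NULL
    )
  })
  names(reports) <- reef_ids
  combined <- data.table::data.table(
    reef_id = reef_ids,
    final_island_area_km2 = vapply(reports, function(r) r$final_island_area_km2, 0),
    plume_union_km2 = vapply(reports, function(r) r$plume_union_km2, 0)
  )
  structure(list(reports = reports, combined = combined),
            class = "campaign_report")
}

#' @export
print.campaign_report <- function(x, ...) {
  cat("<campaign_report>", length(x$reports), "reef(s)\n")
  print(x$combined)
  invisible(x)
}
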