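# Shared fixtures: all built in code, no files.

tiny_grid <- function() scene_grid(9.80, 9.90, 115.40, 115.50)

# Build a scene_series by hand from a ny x nx x nt array for one band
# (others constant), cloud-free unless a cloud array is given.
manual_series <- function(b859, dates, grid = NULL, cloud = NULL) {
  ny <- dim(b859)[1]; nx <- dim(b859)[2]; nt <- dim(b859)[3]
  if (is.null(grid)) grid <- scene_grid(9.80, 9.80 + ny * 250 / 111320,
                                        115.40, 115.40 + nx * 250 / 111320)
  mk <- function(v) array(v, c(ny, nx, nt))
  if (is.null(cloud)) cloud <- array(FALSE, c(ny, nx, nt))
  structure(list(grid = grid, dates = as.Date(dates),
                 bands = list(rrc_469 = mk(0.03), rrc_555 = mk(0.02),
                              rrc_645 = mk(0.008), rrc_859 = b859),
                 cloud = cloud,
                 solar_zenith = rep(30, nt)),
            class = "scene_series")
}

# Exhaustive oracle: dilation as the union of disks planted on every set
# pixel.
brute_dilate <- function(mask, r) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!mask[i, j]) next
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > r^2) next
      y <- i + di; x <- j + dj
      if (y >= 1 && y <= ny && x >= 1 && x <= nx) out[y, x] <- TRUE
    }
  }
  out
}

# An irregular (non-convex) test polygon in lon/lat near the tiny grid.
irregular_polygon <- function() {
  as_polygon(cbind(
    lon = c(115.412, 115.447, 115.433, 115.461, 115.441, 115.418),
    lat = c(9.815, 9.812, 9.838, 9.852, 9.873, 9.861)
  ))
}

# Single-scene config with a reef and an offset plume (mostly deep water),
# used by the delineation-recovery tests.
plume_recovery_config <- function(seed = 3L, cloudy = FALSE) {
  g <- scene_grid(9.80, 9.92, 115.40, 115.58)
  scene_config(g, "2015-06-01", "2015-06-01", seed = seed,
    reefs = list(m = circle_polygon(115.435, 9.86, 1.8)),
    plumes = list(plume_event("m", "2015-06-01",
      center = c(115.435 + 3.2 / 111.32, 9.86), radius_km = 2.52)),
    clouds = if (cloudy) cloud_model(coverage = 0.2))
}

# Independent oracles for the RGB compositor.
block_mean2_oracle <- function(m) {
  ny2 <- nrow(m) / 2; nx2 <- ncol(m) / 2
  out <- matrix(0, ny2, nx2)
  for (i in seq_len(ny2)) for (j in seq_len(nx2)) {
    out[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  out
}

quantize_oracle <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  matrix(as.integer(floor(v * 255 + 0.5)), nrow(v), ncol(v))
}

square_delineation <- function(n_pixels, reef_id = "r", date = "2015-01-01",
                               grid = tiny_grid(), at = c(1L, 1L)) {
  fp <- empty_mask(grid)
  side <- ceiling(sqrt(n_pixels))
  cells <- arrayInd(seq_len(n_pixels), c(side, side))
  fp[cbind(at[1L] + cells[, 1L] - 1L, at[2L] + cells[, 2L] - 1L)] <- TRUE
  plume_delineation(reef_id, date, grid = grid, footprint = fp)
}
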