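test_that("plume_area applies the 1/16 km^2 pixel rule", {
  g <- tiny_grid()
  expect_equal(plume_area(plume_delineation("r", "2015-01-01", grid = g)), 0)
  expect_equal(plume_area(square_delineation(16)), 1.0)
  expect_equal(plume_area(square_delineation(100)), 6.25)
})

test_that("delineation footprints exclude cloud-masked pixels", {
  g <- tiny_grid()
  fp <- empty_mask(g); fp[1:4, 1:4] <- TRUE
  cloud <- empty_mask(g); cloud[1:2, 1:4] <- TRUE
  d <- plume_delineation("r", "2015-01-01", grid = g, footprint = fp,
                         cloud = cloud)
  expect_equal(plume_area(d), 8 / 16)
  expect_false(any(d$footprint & cloud))
})

test_that("auto_delineate finds nothing on uniform clear water", {
  g <- tiny_grid()
  cfg <- scene_config(g, "2015-06-01", "2015-06-01", seed = 12,
                      reefs = list(r = circle_polygon(115.45, 9.85, 0.8)))
  res <- generate_series(cfg)
  ti <- compute_ti(scene_at(res$series, 1))
  d <- auto_delineate(ti, res$truth$reef_mask, matrix(FALSE, g$ny, g$nx),
                      "r", "2015-06-01", g)
  expect_equal(plume_area(d), 0)
  expect_identical(d$source, "auto")
})

test_that("auto_delineate recovers injected plume area within 20%", {
  for (seed in c(3L, 11L)) {
    cfg <- plume_recovery_config(seed = seed)
    res <- generate_series(cfg)
    ti <- compute_ti(scene_at(res$series, 1))
    d <- auto_delineate(ti, res$truth$reef_mask,
                        matrix(FALSE, cfg$grid$ny, cfg$grid$nx),
                        "m", "2015-06-01", cfg$grid)
    truth <- res$truth$plume_area_km2[1]
    expect_lt(abs(plume_area(d) - truth) / truth, 0.20)
  }
})

test_that("auto_delineate never intersects the cloudmask and flags full cloud", {
  cfg <- plume_recovery_config(seed = 4, cloudy = TRUE)
  res <- generate_series(cfg)
  obs <- scene_at(res$series, 1)
  ti <- compute_ti(obs)
  d <- auto_delineate(ti, res$truth$reef_mask, obs$cloud, "m", obs$date,
                      cfg$grid)
  expect_false(any(d$footprint & obs$cloud))
  full <- matrix(TRUE, cfg$grid$ny, cfg$grid$nx)
  d2 <- auto_delineate(ti, res$truth$reef_mask, full, "m", obs$date, cfg$grid)
  expect_equal(plume_area(d2), 0)
  expect_true(attr(d2, "fully_clouded"))
})

test_that("components detached from the reef buffer are excluded", {
  g <- tiny_grid()
  ti <- matrix(0, g$ny, g$nx)
  reef <- empty_mask(g); reef[20, 20] <- TRUE
  ti[19:22, 19:22] <- 0.1           # attached blob
  ti[2:4, 2:4] <- 0.1               # detached blob, far from the reef
  d <- auto_delineate(ti, reef, matrix(FALSE, g$ny, g$nx), "r", "2015-01-01",
                      g, ti_threshold = 0.05)
  expect_true(all(which(d$footprint, arr.ind = TRUE) >= 19))
  expect_equal(sum(d$footprint), 16L)
})

test_that("plume_time_series tabulates areas and rejects duplicates", {
  expect_equal(nrow(plume_time_series(list())), 0L)
  ds <- list(
    square_delineation(16, date = "2015-01-01"),
    square_delineation(32, date = "2015-01-05"),
    plume_delineation("r", "2015-01-09", grid = tiny_grid())  # absent plume
  )
  ts <- plume_time_series(ds)
  expect_equal(nrow(ts), 3L)
  expect_equal(ts$area_km2, c(1.0, 2.0, 0))
  dup <- c(ds, list(square_delineation(4, date = "2015-01-01")))
  expect_error(plume_time_series(dup), "duplicate")
})

test_that("per-date areas over a campaign sum to the truth total", {
  cfg <- scene_config(tiny_grid(), "2015-01-01", "2015-01-20", seed = 31,
    reefs = list(r = circle_polygon(115.45, 9.85, 0.8)),
    plumes = lapply(c("2015-01-03", "2015-01-08", "2015-01-13"), function(d)
      plume_event("r", d, center = c(115.46, 9.86), radius_km = 1)))
  res <- generate_series(cfg)
  ds <- lapply(seq_along(res$series$dates), function(t)
    plume_delineation("r", res$series$dates[t], grid = cfg$grid,
                      footprint = res$truth$plume[, , t]))
  ts <- plume_time_series(ds)
  expect_equal(sum(ts$area_km2), sum(res$truth$plume_area_km2))
})

test_that("frequency map matches a per-pixel counting oracle", {
  ds <- list(
    square_delineation(16, date = "2015-01-01"),
    square_delineation(16, date = "2015-01-02", at = c(3L, 3L)),
    square_delineation(16, date = "2015-01-03", at = c(3L, 3L))
  )
  fm <- plume_frequency_map(ds, n_total_images = 10)
  cc <- ds[[1]]$footprint + ds[[2]]$footprint + ds[[3]]$footprint
  expect_equal(fm, 100 * cc / 10, ignore_attr = TRUE)
  expect_true(all(fm >= 0 & fm <= 100))
  # single delineation, n_total 1 -> covered pixels 100%
  fm1 <- plume_frequency_map(ds[1], n_total_images = 1)
  expect_equal(sort(unique(as.vector(fm1))), c(0, 100))
  expect_error(plume_frequency_map(ds, 0), "> 0")
  expect_error(plume_frequency_map(ds, 2), "smaller")
})

test_that("single-hit fraction matches counting oracles", {
  expect_equal(single_hit_fraction(list(square_delineation(100))), 1.0)
  # two 100-pixel squares overlapping on 25 pixels -> 150/175
  a <- square_delineation(100, date = "2015-01-01")            # rows/cols 1:10
  b <- square_delineation(100, date = "2015-01-02", at = c(6L, 6L))
  expect_equal(sum(a$footprint & b$footprint), 25L)
  expect_equal(single_hit_fraction(list(a, b)), 150 / 175)
  # identical delineations -> nothing hit exactly once
  expect_equal(single_hit_fraction(list(a, square_delineation(100, date = "2015-01-02"))), 0)
  # no coverage at all -> error
  none <- plume_delineation("r", "2015-01-01", grid = tiny_grid())
  expect_error(single_hit_fraction(list(none)), "no pixel")
})

test_that("coverage histogram bookkeeping is conserved", {
  set.seed(8)
  g <- tiny_grid()
  ds <- lapply(1:5, function(i) {
    fp <- matrix(runif(g$ny * g$nx) < 0.2, g$ny, g$nx)
    plume_delineation("r", as.Date("2015-01-01") + i, grid = g, footprint = fp)
  })
  cc <- Reduce(`+`, lapply(ds, function(d) d$footprint + 0L))
  hist <- table(cc[cc > 0])
  expect_equal(sum(hist), sum(cc > 0))
  expect_equal(plume_union_area(ds), sum(cc > 0) / 16)
})
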