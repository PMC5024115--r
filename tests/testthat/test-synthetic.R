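test_that("no-event config yields pure baseline scenes and empty truth", {
  g <- tiny_grid()
  cfg <- scene_config(g, "2015-01-01", "2015-01-10", seed = 1, noise_sd = 0)
  res <- generate_series(cfg)
  expect_length(res$series$dates, 10L)
  expect_false(any(res$truth$island))
  expect_false(any(res$truth$plume))
  expect_false(any(res$truth$cloud))
  sp <- default_spectra()
  expect_equal(res$series$bands$rrc_469[1, 1, ], rep(sp$deep[["rrc_469"]], 10))
  expect_equal(res$series$bands$rrc_859[5, 5, ], rep(sp$deep[["rrc_859"]], 10))
})

test_that("island truth area follows the pixel-count / 16 rule", {
  g <- tiny_grid()
  # 320-pixel final footprint -> 20 km^2
  cfg <- scene_config(g, "2015-01-01", "2015-12-31", revisit = 30, seed = 2,
    islands = list(island_event("r", "2015-02-01", "2015-10-01",
                                center = c(115.45, 9.85), area_km2 = 20)))
  res <- generate_series(cfg)
  nt <- length(res$series$dates)
  final <- res$truth$island[, , nt]
  expect_equal(sum(final), 320L)
  expect_equal(sum(final) / 16, 20)
})

test_that("Mischief-like fixture recovers the configured final area", {
  g <- scene_grid(9.80, 9.98, 115.44, 115.64)
  cfg <- scene_config(g, "2014-06-01", "2015-12-31", revisit = 15, seed = 5,
    islands = list(island_event("Mischief Reef", "2015-01-01", "2015-12-01",
                                center = c(115.54, 9.90), area_km2 = 6.39)))
  res <- generate_series(cfg)
  nt <- length(res$series$dates)
  got <- sum(res$truth$island[, , nt]) / 16
  # exact to the nearest whole pixel (1/16 km^2 grid quantisation)
  expect_lt(abs(got - 6.39), 1 / 16)
})

test_that("identical config and seed give bit-identical output", {
  g <- tiny_grid()
  mk <- function() {
    cfg <- scene_config(g, "2015-01-01", "2015-01-20", seed = 77,
      reefs = list(r = circle_polygon(115.45, 9.85, 1)),
      islands = list(island_event("r", "2015-01-05", "2015-01-15",
                                  center = c(115.45, 9.85), area_km2 = 0.5)),
      plumes = list(plume_event("r", "2015-01-10", center = c(115.46, 9.86),
                                radius_km = 1)),
      glints = list(glint_event("2015-01-12", 0.05)),
      clouds = cloud_model(0.3))
    generate_series(cfg)
  }
  a <- mk(); b <- mk()
  expect_identical(a$series, b$series)
  expect_identical(a$truth, b$truth)
})

test_that("generate_series does not disturb the caller's RNG stream", {
  set.seed(123); r1 <- runif(3)
  set.seed(123); invisible(runif(0))
  cfg <- scene_config(tiny_grid(), "2015-01-01", "2015-01-02", seed = 9,
                      clouds = cloud_model(0.3))
  generate_series(cfg)
  r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("island truth mask is non-decreasing in time", {
  g <- tiny_grid()
  cfg <- scene_config(g, "2015-01-01", "2015-06-30", revisit = 7, seed = 3,
    islands = list(island_event("r", "2015-02-01", "2015-05-01",
                                center = c(115.45, 9.85), area_km2 = 2)))
  res <- generate_series(cfg)
  nt <- length(res$series$dates)
  for (t in 2:nt) {
    expect_true(all(res$truth$island[, , t] >= res$truth$island[, , t - 1L]))
  }
  # growth fraction endpoints
  first_in <- which(res$series$dates >= as.Date("2015-05-01"))[1]
  expect_equal(sum(res$truth$island[, , first_in]), 32L)  # 2 km^2 * 16
  before <- which(res$series$dates < as.Date("2015-02-01"))
  expect_false(any(res$truth$island[, , before]))
})

test_that("clouds occlude the observation but not the truth", {
  g <- tiny_grid()
  cfg <- scene_config(g, "2015-01-01", "2015-01-03", seed = 4, noise_sd = 0,
    islands = list(island_event("r", "2015-01-01", "2015-01-01",
                                center = c(115.45, 9.85), area_km2 = 1)),
    clouds = cloud_model(coverage = 1))
  res <- generate_series(cfg)
  sp <- default_spectra()
  expect_true(all(res$series$bands$rrc_859 == sp$cloud[["rrc_859"]]))
  expect_true(all(res$truth$cloud))
  expect_equal(sum(res$truth$island[, , 2]), 16L)  # recorded despite cloud
})

test_that("plume truth area equals mask pixel count / 16 on every date", {
  cfg <- plume_recovery_config(seed = 8, cloudy = TRUE)
  res <- generate_series(cfg)
  for (t in seq_along(res$series$dates)) {
    expect_equal(res$truth$plume_area_km2[t], sum(res$truth$plume[, , t]) / 16)
  }
})

test_that("injected plume pixels have TI strictly above co-located clear water", {
  cfg <- plume_recovery_config(seed = 10)
  base_cfg <- cfg
  base_cfg$plumes <- list()
  res <- generate_series(cfg)
  base <- generate_series(base_cfg)
  ti_p <- compute_ti(scene_at(res$series, 1))
  ti_0 <- compute_ti(scene_at(base$series, 1))
  pm <- res$truth$plume[, , 1]
  # same seed => same noise realisation; the plume offset alone separates them
  expect_true(all(ti_p[pm] > ti_0[pm]))
})

test_that("event validation rejects bad configs", {
  g <- tiny_grid()
  expect_error(
    scene_config(g, "2015-01-01", "2015-01-10", seed = 1,
      islands = list(island_event("r", "2015-02-01", "2015-03-01",
                                  center = c(115.45, 9.85), area_km2 = 1))),
    "outside the series date_range")
  expect_error(
    scene_config(g, "2015-01-01", "2015-01-10", seed = 1,
      plumes = list(plume_event("r", "2016-01-01", center = c(115.45, 9.85),
                                radius_km = 1))),
    "outside the series date_range")
  cfg <- scene_config(g, "2015-01-01", "2015-01-05", seed = 1,
    islands = list(
      island_event("a", "2015-01-02", "2015-01-04",
                   center = c(115.45, 9.85), area_km2 = 1),
      island_event("b", "2015-01-02", "2015-01-04",
                   center = c(115.4505, 9.8505), area_km2 = 1)))
  expect_error(generate_series(cfg), "overlapping island footprints")
  sp <- default_spectra(); sp$land[1] <- 2
  expect_error(scene_config(g, "2015-01-01", "2015-01-02", spectra = sp),
               "\\[0, 1.5\\]")
})

test_that("scene_at extracts a consistent observation", {
  cfg <- scene_config(tiny_grid(), "2015-03-01", "2015-03-05", seed = 6,
                      clouds = cloud_model(0.2))
  res <- generate_series(cfg)
  obs <- scene_at(res$series, as.Date("2015-03-03"))
  expect_s3_class(obs, "scene_observation")
  expect_equal(obs$rrc_645, res$series$bands$rrc_645[, , 3])
  expect_equal(obs$cloud, res$series$cloud[, , 3])
  expect_error(scene_at(res$series, as.Date("2015-04-01")), "not present")
})
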