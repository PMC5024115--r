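test_that("the packaged summary table parses into 15 validated records", {
  rec <- load_island_records(island_records_fixture())
  expect_equal(nrow(rec), 15L)
  expect_equal(sum(rec$country == "C"), 7L)
  expect_equal(sum(rec$country == "V"), 7L)
  expect_equal(sum(rec$country == "T"), 1L)
  # expansion rows keep both the total island area and the added area
  spratly <- rec[rec$reef_name == "Spratly Island"]
  expect_equal(spratly$island_area_km2, 0.33)
  expect_equal(spratly$new_area_km2, 0.17)
  # censored "<0.01" entries become (0, 0.01) intervals
  pearson <- rec[rec$reef_name == "Pearson Reef"]
  expect_true(pearson$new_area_censored)
  expect_true(is.na(pearson$new_area_km2))
  expect_equal(pearson$new_area_upper_km2, 0.01)
  # date sentinels are first-class
  expect_equal(rec[rec$reef_name == "West Reef"]$start_sentinel, "Pre-OLI")
  expect_equal(rec[rec$reef_name == "Cornwallis South Reef"]$end_sentinel, "Ongoing")
  expect_equal(rec[rec$reef_name == "Mischief Reef"]$start_date,
               as.Date("2015-01-01"))
})

test_that("empty and malformed inputs are handled", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("reef_name,country,lat,lon,reef_area_km2,island_area_km2,new_area_km2,start,end", tmp)
  expect_equal(nrow(load_island_records(tmp)), 0L)
  writeLines(c(
    "reef_name,country,lat,lon,reef_area_km2,island_area_km2,new_area_km2,start,end",
    "Some Reef,X,9.0,114.0,1.0,0.5,0.5,Jan 2015,Dec 2015"), tmp)
  expect_error(load_island_records(tmp), "row 1.*country")
  writeLines(c(
    "reef_name,country,lat,lon,reef_area_km2,island_area_km2,new_area_km2,start,end",
    "Some Reef,C,9.0,114.0,1.0,0.5,abc,Jan 2015,Dec 2015"), tmp)
  expect_error(load_island_records(tmp), "row 1.*new_area_km2")
  writeLines(c(
    "reef_name,country,lat,lon,reef_area_km2,island_area_km2,new_area_km2,start,end",
    "Some Reef,C,9.0,114.0,1.0,0.5,0.6,Jan 2015,Dec 2015"), tmp)
  expect_error(load_island_records(tmp), "new_area_km2 must lie")
  writeLines(c(
    "reef_name,country,lat,lon,reef_area_km2,island_area_km2,new_area_km2,start,end",
    "Some Reef,C,9.0,114.0,1.0,0.5,0.5,Januaryish 2015,Dec 2015"), tmp)
  expect_error(load_island_records(tmp), "row 1.*start")
})

test_that("country totals sum exactly where the column is exact", {
  rec <- load_island_records(island_records_fixture())
  tot <- country_totals(rec)
  china <- tot[tot$country == "C"]
  expect_equal(china$total_new_area_km2, 14.52, tolerance = 1e-12)
  expect_equal(china$n_censored, 0L)
  vietnam <- tot[tot$country == "V"]
  expect_equal(vietnam$n_censored, 2L)       # two "<0.01" projects
  expect_equal(vietnam$total_new_area_km2, 0.52)  # exact-sum lower bound
  expect_equal(tot[tot$country == "T"]$total_new_area_km2, 0.06)
  expect_equal(nrow(country_totals(rec[0])), 0L)
  bad <- data.table::copy(rec); bad$country[1] <- "Z"
  expect_error(country_totals(bad), "unknown country")
})

test_that("totals are permutation-invariant and additive", {
  rec <- load_island_records(island_records_fixture())
  set.seed(2)
  shuffled <- rec[sample(nrow(rec))]
  a <- country_totals(rec); b <- country_totals(shuffled)
  data.table::setkey(a, country); data.table::setkey(b, country)
  expect_equal(a, b)
  half1 <- country_totals(rec[country == "C"])
  half2 <- country_totals(rec[country != "C"])
  expect_equal(half1[country == "C"]$total_new_area_km2,
               a[country == "C"]$total_new_area_km2)
  expect_equal(sum(half1$total_new_area_km2) + sum(half2$total_new_area_km2),
               sum(a$total_new_area_km2))
})

test_that("records outside the configured grid are flagged, not dropped", {
  rec <- load_island_records(island_records_fixture())
  grid <- scene_grid(8.5, 11.5, 112, 116)
  flagged <- flag_outside_grid(rec, grid)
  expect_equal(nrow(flagged), 15L)
  expect_false(flagged[flagged$reef_name == "Spratly Island"]$in_grid)
  expect_true(flagged[flagged$reef_name == "Mischief Reef"]$in_grid)
  expect_equal(sum(!flagged$in_grid), 1L)
})

test_that("campaign reports bundle trajectories, plumes and totals", {
  traj <- data.table::data.table(
    reef_id = rep(c("a", "b", "c"), each = 3),
    date = rep(as.Date("2015-01-01") + c(0, 10, 20), 3),
    area_km2 = c(0, 1, 2, 0, 0.5, 0.5, 0, 0, 0))
  plumes <- list(square_delineation(16, reef_id = "a", date = "2015-01-05"),
                 square_delineation(32, reef_id = "a", date = "2015-01-15"))
  rep3 <- campaign_report(traj, plumes = plumes)
  expect_length(rep3$reports, 3L)
  expect_equal(nrow(rep3$combined), 3L)
  expect_equal(rep3$reports$a$final_island_area_km2, 2)
  expect_equal(nrow(rep3$reports$a$plume_series), 2L)
  expect_equal(rep3$reports$b$plume_union_km2, 0)
  expect_equal(nrow(rep3$reports$c$plume_series), 0L)  # no plumes, section empty
  expect_error(campaign_report(traj, plumes = list(
    square_delineation(4, reef_id = "zzz"))), "unknown reef")
})

test_that("a synthetic campaign report recovers the truth island area", {
  cfg <- scene_config(scene_grid(9.80, 9.98, 115.44, 115.64),
    "2014-10-01", "2015-12-31", revisit = 15, seed = 14,
    islands = list(island_event("Mischief-like", "2015-01-01", "2015-12-01",
                                center = c(115.54, 9.90), area_km2 = 6.39)))
  res <- generate_series(cfg)
  traj <- data.table::data.table(
    reef_id = "Mischief-like",
    date = res$series$dates,
    area_km2 = apply(res$truth$island, 3, sum) / 16)
  rep1 <- campaign_report(traj)
  expect_lt(abs(rep1$reports[["Mischief-like"]]$final_island_area_km2 - 6.39),
            0.0625)
})
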