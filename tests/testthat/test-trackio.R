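# helpers to build Movebank-dialect CSVs in code
write_fix_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  header <- "individual-local-identifier,timestamp,location-long,location-lat"
  writeLines(c(header, rows), path)
  path
}

fix_tbl <- function(bird, times, lon, lat) {
  tibble::tibble(bird_id = bird,
                 timestamp = as.POSIXct(times, tz = "UTC"),
                 lon = lon, lat = lat)
}

test_that("read_fixes parses, sorts, deduplicates and validates", {
  p <- write_fix_csv(c("3029,2017-09-05 10:05:00,-5.1,37.2",
                       "3029,2017-09-05 10:00:00,-5.0,37.0"))
  fx <- read_fixes(p)
  expect_equal(nrow(fx), 2)
  expect_equal(attr(fx, "read_report")$birds, 1)
  expect_true(all(diff(fx$timestamp) > 0))

  # duplicated timestamp collapses to the first row
  p <- write_fix_csv(c("A,2017-09-05 10:00:00,-5.0,37.0",
                       "A,2017-09-05 10:00:00,-5.5,37.5",
                       "A,2017-09-05 10:05:00,-5.1,37.1"))
  fx <- read_fixes(p)
  expect_equal(nrow(fx), 2)
  expect_equal(attr(fx, "read_report")$duplicates_dropped, 1)
  expect_equal(fx$lon[1], -5.0)

  # invalid latitude names the row
  p <- write_fix_csv(c("A,2017-09-05 10:00:00,-5.0,95"))
  expect_error(read_fixes(p), "latitude.*1")
  # unparseable timestamp names the row
  p <- write_fix_csv(c("A,not-a-time,-5.0,37"))
  expect_error(read_fixes(p), "timestamp")
  # missing mandatory column is fatal
  p <- tempfile(fileext = ".csv")
  writeLines(c("id,timestamp", "A,2017-09-05 10:00:00"), p)
  expect_error(read_fixes(p), "missing mandatory column")
})

test_that("kinematics follow distance/time arithmetic with the incoming convention", {
  # 2.5 km in 5 minutes is 30 km/h
  d <- 2.5 / 111.1950787          # degrees of latitude covering 2.5 km
  fx <- annotate_kinematics(fix_tbl("A",
    c("2017-10-01 10:00:00", "2017-10-01 10:05:00"), c(0, 0), c(37, 37 + d)))
  expect_true(is.na(fx$speed_kmh[1]))
  expect_equal(fx$dt_min[2], 5)
  expect_equal(fx$speed_kmh[2], 30, tolerance = 1e-6)

  # single-fix bird: no kinematics, no error
  fx <- annotate_kinematics(fix_tbl("A", "2017-10-01 10:00:00", 0, 37))
  expect_true(is.na(fx$dt_min))

  # three fixes on a meridian 0.1 degrees apart at 10-minute spacing
  fx <- annotate_kinematics(fix_tbl("A",
    c("2017-10-01 10:00:00", "2017-10-01 10:10:00", "2017-10-01 10:20:00"),
    c(0, 0, 0), c(37.0, 37.1, 37.2)))
  expect_equal(fx$dist_km[2:3], rep(6371.0088 * 0.1 * pi / 180, 2),
               tolerance = 1e-9)
  expect_equal(fx$speed_kmh[2:3], rep(6371.0088 * 0.1 * pi / 180 * 6, 2),
               tolerance = 1e-9)
})

test_that("winter-box stage drops birds wintering outside the box", {
  inside <- fix_tbl("in", sprintf("2017-12-%02d 12:00:00", 1:28),
                    rep(-5, 28), rep(37, 28))
  outside <- fix_tbl("out", sprintf("2017-12-%02d 12:00:00", 1:28),
                     rep(5, 28), rep(45, 28))
  fx <- filter_cascade(dplyr::bind_rows(inside, outside),
                       filter_config(min_fixes_per_birdyear = 1))
  expect_setequal(unique(fx$bird_id), "in")
  rep_ <- attr(fx, "filter_report")$stages
  expect_equal(rep_$n_dropped[rep_$stage == "winter_box"], 28)
})

test_that("sampling-interval stage thins a 1-minute cadence to > 4 minutes", {
  fx <- fix_tbl("A", as.POSIXct("2017-12-01 10:00:00", tz = "UTC") + 60 * (0:59),
                rep(-5, 60), rep(37, 60))
  out <- filter_cascade(fx, filter_config(min_fixes_per_birdyear = 1))
  expect_gt(nrow(out), 1)
  expect_true(all(out$dt_min[-1] > 4))
})

test_that("speed stage removes a spike and relinks neighbours below the ceiling", {
  # 5-fix toy at 5-min cadence moving north at 30 km/h, with fix 3 displaced
  # so that steps 2->3 and 3->4 imply ~250 km/h
  step <- 2.5 / 111.1950787
  lat <- 37 + step * (0:4)
  lat[3] <- lat[3] + 250 / 60 * 5 / 111.1950787   # ~20.8 km extra
  fx <- fix_tbl("A", as.POSIXct("2017-12-01 10:00:00", tz = "UTC") + 300 * (0:4),
                rep(-5, 5), lat)
  out <- filter_cascade(fx, filter_config(min_fixes_per_birdyear = 1))
  expect_equal(nrow(out), 4)
  expect_false(any(out$speed_kmh > 100, na.rm = TRUE))
  # relinked step spans 10 minutes and 5 km: 30 km/h
  expect_equal(out$speed_kmh[3], 30, tolerance = 1e-6)
})

test_that("bird-years split on the September boundary and label as id-year", {
  fx <- fix_tbl("3029",
                c("2017-09-05 10:00:00", "2018-03-20 10:00:00",
                  "2019-10-01 10:00:00", "2020-10-01 10:00:00"),
                rep(-5, 4), rep(37, 4))
  out <- split_bird_years(fx)
  expect_equal(out$birdyear,
               c("3029-2017", "3029-2017", "3029-2019", "3029-2020"))
  expect_error(
    split_bird_years(fix_tbl("A", "2018-04-02 10:00:00", -5, 37)),
    "season")
})

test_that("filter cascade is idempotent and conserves per-bird counts", {
  sc <- track_scenario(noise_m = 10, gap_per_day = 0.05, n_birds = 2)
  cfg <- filter_config(min_fixes_per_birdyear = 100)
  once <- filter_cascade(sc$tracks$fixes, cfg)
  twice <- filter_cascade(once, cfg)
  expect_equal(nrow(twice), nrow(once))
  expect_equal(twice$timestamp, once$timestamp)
  # post-conditions
  expect_true(all(once$dt_min[!once$segment_start] > 4, na.rm = TRUE))
  expect_true(all(once$speed_kmh <= 100, na.rm = TRUE))
  # conservation: drops plus survivors equal the input, per bird
  rep_ <- attr(once, "filter_report")
  for (b in unique(sc$tracks$fixes$bird_id)) {
    dropped <- sum(rep_$by_bird$n_dropped[rep_$by_bird$bird_id == b])
    expect_equal(dropped + sum(once$bird_id == b),
                 sum(sc$tracks$fixes$bird_id == b))
  }
})
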