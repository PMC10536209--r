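test_that("reading a weather table validates, sorts and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmin,tmax",
               "2001-01-03,4.25,9.125",
               "2001-01-01,2.5,8.75",
               "2001-01-02,3.1,7.9"), path)
  ws <- read_daily_weather(path, site_id = "toy")
  expect_s3_class(ws, "weather_series")
  expect_equal(nrow(ws), 3L)
  expect_equal(ws$date, as.Date("2001-01-01") + 0:2)  # sorted on read
  expect_equal(ws$tmean, (ws$tmin + ws$tmax) / 2)     # derived mean
  expect_true(attr(ws, "tmean_derived"))

  out <- withr::local_tempfile(fileext = ".csv")
  write_daily_weather(ws, out)
  back <- read_daily_weather(out, site_id = "toy")
  expect_identical(back$tmin, ws$tmin)
  expect_identical(back$tmax, ws$tmax)
})

test_that("malformed weather tables are rejected with informative errors", {
  gap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmin,tmax", "2001-01-01,2,8", "2001-01-03,2,8"), gap)
  expect_error(read_daily_weather(gap), "2001-01-02")

  inverted <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmin,tmax", "2001-01-01,10,5"), inverted)
  expect_error(read_daily_weather(inverted), "tmin > tmax at row 1")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmin", "2001-01-01,2"), nocol)
  expect_error(read_daily_weather(nocol), "tmax")

  expect_error(weather_series(as.Date("2001-01-01"), 2, 8, tmean = 9),
               "tmean")
})

test_that("dormancy seasons cover exactly November through October", {
  ws <- const_series(2, 8, "1996-01-01", "1998-12-31")
  season <- build_dormancy_season(ws, 1998)
  expect_s3_class(season, "dormancy_season")
  expect_equal(season$date[1L], as.Date("1997-11-01"))
  expect_equal(season$date[nrow(season)], as.Date("1998-10-31"))
  expect_equal(nrow(season), 365L)

  # leap phenology year contains Feb 29 -> 366 days
  leap <- build_dormancy_season(const_series(2, 8, "1999-01-01",
                                             "2000-12-31"), 2000)
  expect_equal(nrow(leap), 366L)

  expect_error(build_dormancy_season(const_series(2, 8, "1998-01-01",
                                                  "1998-12-31"), 1998),
               "season window")
})

test_that("climatologies average by calendar day and drop Feb 29", {
  d <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = "day")
  doy <- as.integer(format(d, "%j"))
  yr <- as.integer(format(d, "%Y"))
  tmin <- ifelse(yr == 2001, 0, 2) + 0 * doy
  ws <- weather_series(d, tmin, tmin + 10)
  clim <- build_climatology(ws, 2001:2002)
  expect_equal(nrow(clim), 365L)
  expect_equal(clim$tmin, rep(1, 365))  # mean of 0 and 2
  expect_equal(clim$tmax, rep(11, 365))

  # identical years reproduce either year; a leap year still yields 365
  ws2 <- const_series(3, 9, "1999-01-01", "2000-12-31")
  clim2 <- build_climatology(ws2, 1999:2000)
  expect_equal(nrow(clim2), 365L)
  expect_equal(clim2$tmin, rep(3, 365))

  expect_error(build_climatology(ws, 2000:2002), "cover")
})

test_that("climatology building is idempotent on a replicated mean year", {
  clim <- toy_climatology()
  # lay the 365-day mean year out over two non-leap years and re-average
  d <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = "day")
  idx <- rep(1:365, 2)
  ws <- weather_series(d, clim$tmin[idx], clim$tmax[idx])
  again <- build_climatology(ws, 2001:2002)
  expect_equal(again$tmin, clim$tmin)
  expect_equal(again$tmax, clim$tmax)
})

test_that("grid files round-trip and reject irregular axes", {
  grid <- gradient_grid(c(40.05, 40.15), c(8.05, 8.15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_temperature_grid(grid, path)
  back <- load_temperature_grid(path)
  expect_equal(back$latitudes, grid$latitudes)
  expect_identical(back$tmin, grid$tmin)
  expect_equal(back$kind, "climatology")

  expect_error(temperature_grid(c(40.0, 40.1, 40.3), c(8.0, 8.1),
                                array(0, c(3, 2, 365)),
                                array(1, c(3, 2, 365)), 1:365),
               "irregular")

  # window subset on read keeps only requested longitudes
  sub <- load_temperature_grid(path, lon_range = c(8.0, 8.1))
  expect_equal(sub$longitudes, 8.05)
})

test_that("extract_cell matches nearest center, breaks ties low, bounds-checks", {
  grid <- gradient_grid(c(40.05, 40.15, 40.25), c(8.05, 8.15))
  # exact center
  cell <- extract_cell(grid, 40.15, 8.15)
  expect_equal(attr(cell, "latitude"), 40.15)
  expect_equal(cell$tmin, grid$tmin[2, 2, ])
  # equidistant point -> lower index (southern cell)
  mid <- extract_cell(grid, 40.10, 8.05)
  expect_equal(attr(mid, "latitude"), 40.05)
  # every center maps to its own cell
  for (i in 1:3) for (j in 1:2) {
    c_ij <- extract_cell(grid, grid$latitudes[i], grid$longitudes[j])
    expect_equal(c_ij$tmax, grid$tmax[i, j, ])
  }
  expect_error(extract_cell(grid, 50, 8.05), "outside")
})
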