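test_that("daily GDD clamps the extremes before averaging", {
  p <- gdd_params(tb = 5, tx_base = 30, hr = 100)
  expect_equal(daily_gdd(15, 25, p), 15)
  expect_equal(daily_gdd(25, 35, p), 22.5)   # tmax clamps to 30
  expect_equal(daily_gdd(5, 5, p), 0)        # both at the base
  expect_equal(daily_gdd(-10, 0, p), 0)      # both clamp up to the base
  expect_error(daily_gdd(10, 5, p), "tmin > tmax")
})

test_that("daily GDD is non-negative, monotone, and saturates above tx_base", {
  p <- gdd_params(5, 30, 100)
  set.seed(77)
  tn <- runif(500, -10, 35)
  tx <- tn + runif(500, 0, 12)
  g <- daily_gdd(tn, tx, p)
  expect_true(all(g >= 0))
  expect_true(all(daily_gdd(tn + 1, tx + 1, p) >= g))     # warming
  expect_equal(daily_gdd(pmax(tn, 31), pmax(tx, 32), p),
               daily_gdd(pmax(tn, 31) + 5, pmax(tx, 32) + 5, p))  # saturated
})

test_that("GDD accumulation starts the day after the event and finds fulfillment", {
  season <- block_season(lens = 365, tmins = 10, tmaxs = 20)  # 10 GDD/day
  p <- gdd_params(5, 30, 60)
  start <- season$date[20]
  traj <- accumulate_gdd(season, start, p)
  expect_equal(traj$date[1L], start + 1)           # event day excluded
  expect_equal(attr(traj, "fulfillment_day"), season$date[26])  # 6 days later
  expect_true(all(diff(traj$cumulative) >= 0))

  pred <- predict_phase_date(season, start, p, "blooming")
  expect_equal(pred$jday, 26L - 61L)

  # requirement out of reach and start on the last day both fail cleanly
  coldp <- gdd_params(25, 30, 60)
  expect_equal(predict_phase_date(season, start, coldp)$status,
               "requirement-not-met")
  last <- predict_phase_date(season, season$date[nrow(season)], p)
  expect_equal(last$status, "requirement-not-met")
  expect_error(accumulate_gdd(season, as.Date("2005-01-01"), p), "window")
})

test_that("the full chain predicts ordered sprouting, blooming and pit hardening", {
  # 10 cold days (-3/d chill to Cr=-30), 5 warm days (+6/d anti-chill),
  # then 10 GDD/day: sprout day 15, bloom day 21 (Hr 60), pit day 25 (Hr 100)
  season <- block_season(lens = c(10, 5), tmins = c(2, 12, 10),
                         tmaxs = c(8, 20, 20))
  cv <- cultivar_params("toy", "early", cac_params(10, -30),
                        gdd_params(5, 30, 60), gdd_params(5, 30, 100))
  chain <- predict_chain(season, cv)
  expect_equal(chain$sprouting$jday, 15L - 61L)
  expect_equal(chain$blooming$jday, 21L - 61L)
  expect_equal(chain$pit_hardening$jday, 25L - 61L)
  expect_lte(chain$sprouting$jday, chain$blooming$jday)
  expect_lte(chain$blooming$jday, chain$pit_hardening$jday)

  # an observed sprouting date overrides the chill model
  forced <- predict_chain(season, cv, start_override = season$date[12])
  expect_equal(forced$sprouting$date, season$date[12])
  # from day 13: 11 GDD/day on days 13-15, then 10/day; >= 60 on day 18
  expect_equal(forced$blooming$jday, 18L - 61L)
})

test_that("sprouting failure propagates to every downstream phase", {
  warm <- block_season(lens = 365, tmins = 12, tmaxs = 20)
  cv <- cultivar_params("toy", "early", cac_params(10, -30),
                        gdd_params(5, 30, 60), gdd_params(5, 30, 100))
  chain <- predict_chain(warm, cv)
  expect_equal(chain$sprouting$status, "requirement-not-met")
  expect_equal(chain$blooming$status, "requirement-not-met")
  expect_equal(chain$pit_hardening$status, "requirement-not-met")
})

test_that("pit hardening never precedes blooming on random seasons", {
  cv <- cultivar_params("toy", "early", cac_params(10, -60),
                        gdd_params(5, 30, 150), gdd_params(5, 30, 151))
  set.seed(88)
  for (k in 1:10) {
    clim <- toy_climatology(annual_mean = runif(1, 12, 19),
                            amplitude = runif(1, 7, 11))
    season <- climatology_season(clim)
    chain <- predict_chain(season, cv)
    if (chain$pit_hardening$status == "success") {
      expect_gte(chain$pit_hardening$jday, chain$blooming$jday)
      expect_gte(chain$blooming$jday, chain$sprouting$jday)
    }
  }
})

test_that("cultivar parameter invariants are enforced", {
  cacp <- cac_params(10, -100)
  expect_error(cultivar_params("x", "early", cacp,
                               gdd_params(5, 30, 400), gdd_params(6, 30, 900)),
               "share")
  expect_error(cultivar_params("x", "early", cacp,
                               gdd_params(5, 30, 400), gdd_params(5, 30, 300)),
               "exceed")
  expect_error(gdd_params(10, 10, 100), "below")
  expect_error(gdd_params(5, 30, 0), "positive")
  expect_error(cac_params(-1, -100), "positive")
  expect_error(cac_params(10, 5), "negative")
})

test_that("cultivar parameter files round-trip through YAML", {
  cv <- reference_cultivar("Frantoio")
  path <- withr::local_tempfile(fileext = ".yml")
  write_cultivar_params(cv, path)
  back <- read_cultivar_params(path)
  expect_equal(back, cv)
})
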