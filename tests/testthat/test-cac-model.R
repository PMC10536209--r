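test_that("six-case closed forms reproduce the frozen reference values", {
  cases <- data.frame(
    tmin = c(-8,  2,    2,   -5,   12),
    tmax = c(-2,  8,   12,    5,   20),
    cd   = c( 0, -3, -4.8, -1.25,   0),
    ca   = c( 0,  0,  0.2,    0,    6),
    case = c( 6,  3,    2,    4,    1))
  got <- chill_anti_chill(cases$tmin, cases$tmax, tc = 10)
  expect_equal(got$cd, cases$cd, tolerance = 1e-12)
  expect_equal(got$ca, cases$ca, tolerance = 1e-12)
  expect_equal(got$case, cases$case)
  expect_error(chill_anti_chill(10, 5, tc = 10), "tmin > tmax")
  expect_error(chill_anti_chill(2, 8, tc = -1), "positive")
})

test_that("closed forms agree with the triangle integration oracle", {
  set.seed(401)
  for (k in 1:500) {
    tn <- runif(1, -15, 25)
    tx <- tn + runif(1, 0, 15)
    tc <- runif(1, 1, 14)
    exact <- chill_anti_chill(tn, tx, tc)
    approx <- triangle_oracle(tn, tx, tc, n_steps = 20000L)
    expect_lt(abs(exact$cd - approx$cd), 1e-3)
    expect_lt(abs(exact$ca - approx$ca), 1e-3)
  }
})

test_that("chill is never positive and anti-chill never negative", {
  set.seed(402)
  tn <- runif(2000, -20, 30)
  tx <- tn + runif(2000, 0, 18)
  for (tc in c(2, 7, 9.5, 14)) {
    got <- chill_anti_chill(tn, tx, tc)
    expect_true(all(got$cd <= 0))
    expect_true(all(got$ca >= 0))
    expect_true(all(got$case %in% 1:6))
  }
})

test_that("degenerate flat days take the limiting value without dividing by zero", {
  flat <- chill_anti_chill(5, 5, tc = 10)
  expect_equal(flat$cd, 0)  # zero-width triangle has no area
  expect_equal(flat$ca, 0)
  # a frozen flat day
  expect_equal(unlist(chill_anti_chill(-3, -3, tc = 10)[1, 1:2]),
               c(cd = 0, ca = 0))
  # oracle agrees on the zero-width triangle
  o <- triangle_oracle(5, 5, 10)
  expect_equal(flat$cd, o$cd, tolerance = 1e-9)
})

test_that("a supplied daily mean replaces the symmetric mean in cases 1-3 only", {
  with_mean <- chill_anti_chill(2, 8, tc = 10, tmean = 6)
  expect_equal(with_mean$cd, -(6 - 2))                # case 3 uses tmean
  cross <- chill_anti_chill(-5, 5, tc = 10, tmean = 1)
  expect_equal(cross$cd, -25 / 20)                    # case 4 ignores it
})

test_that("sequential accumulation finds release and sprouting days", {
  # 3 chill units/day for 10 days reaches Cr = -30, then 6 anti-chill/day
  season <- block_season(lens = c(10), tmins = c(2, 12), tmaxs = c(8, 20))
  traj <- accumulate_cac(season, cac_params(tc = 10, cr = -30))
  expect_equal(attr(traj, "endo_release_day"), as.Date("2001-11-10"))
  expect_equal(attr(traj, "sprouting_day"), as.Date("2001-11-15"))
  s <- traj$cumulative
  expect_true(all(diff(s[traj$phase == 1L]) <= 0))  # non-increasing
  expect_true(all(diff(s[traj$phase == 2L]) >= 0))  # non-decreasing
  expect_equal(s[10], -30)
  expect_equal(s[15], 0)

  pred <- predict_sprouting(season, cac_params(10, -30))
  expect_equal(pred$status, "success")
  expect_equal(pred$jday, 15L - 61L)  # season day 15 -> jday -46
})

test_that("unmet requirements yield explicit failures, not dates", {
  # always warm: case 1 only, no chill ever accumulates
  warm <- block_season(lens = 365, tmins = 12, tmaxs = 20)
  traj <- accumulate_cac(warm, cac_params(10, -30))
  expect_true(is.na(attr(traj, "endo_release_day")))
  expect_equal(predict_sprouting(warm, cac_params(10, -30))$status,
               "requirement-not-met")

  # hyper-cold: chilling fulfilled via case-4 days but anti-chill never accrues
  cold <- block_season(lens = 365, tmins = -10, tmaxs = 2)
  pred <- predict_sprouting(cold, cac_params(10, -30))
  expect_equal(pred$status, "requirement-not-met")
  expect_true(is.na(pred$jday))
})

test_that("warming the forcing period never delays sprouting", {
  params <- cac_params(10, -30)
  base <- block_season(lens = c(10), tmins = c(2, 12), tmaxs = c(8, 20))
  ref <- predict_sprouting(base, params)$jday
  for (delta in c(0.5, 1, 2, 5)) {
    warmer <- block_season(lens = c(10), tmins = c(2, 12 + delta),
                           tmaxs = c(8, 20 + delta))
    expect_lte(predict_sprouting(warmer, params)$jday, ref)
  }
})

test_that("trajectories export to CSV with the expected columns", {
  season <- block_season(lens = c(10), tmins = c(2, 12), tmaxs = c(8, 20))
  traj <- accumulate_cac(season, cac_params(10, -30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read.csv(path)
  expect_equal(names(back), c("date", "cd", "ca", "cumulative", "phase"))
  expect_equal(nrow(back), nrow(season))
})
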