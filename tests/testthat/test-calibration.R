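test_that("rmse follows its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(10, 13), 3)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:2), "equal")
})

make_toy_dataset <- function(noise = 0, seed = 21, phases = "sprouting") {
  cv <- reference_cultivar("Carolea")
  net <- simulate_site_network(site_climate(seed = seed), c(-2, 0, 2),
                               2000:2002)
  simulate_observations(cv, net, 2001:2002, obs_noise_sd = noise,
                        seed = seed, phases = phases)
}

test_that("objectives are zero on self-consistent data and track shifts", {
  so <- make_toy_dataset()
  ds <- so$dataset
  truth <- so$true_params
  expect_equal(cac_objective(truth$cac, ds), 0)

  shifted <- ds
  shifted$observations$jday <- shifted$observations$jday + 1L
  expect_equal(cac_objective(truth$cac, shifted), 1)

  # parameters that can never be satisfied earn the Oct-31 penalty
  hopeless <- cac_params(tc = 14, cr = -3000)
  pen <- cac_objective(hopeless, ds)
  expect_true(is.finite(pen))
  expect_equal(pen, rmse(rep(304, nrow(ds$observations)),
                         ds$observations$jday))
})

test_that("the GDD objective starts from each observed sprouting date", {
  so <- make_toy_dataset(phases = c("sprouting", "blooming"))
  ds <- so$dataset
  bloom <- ds$observations[ds$observations$phase == "blooming", ]
  bds <- pheno_dataset(bloom, ds$seasons)
  expect_equal(gdd_objective(so$true_params$gdd_bloom, bds), 0)
  shifted <- bds
  shifted$observations$jday <- shifted$observations$jday - 2L
  expect_equal(gdd_objective(so$true_params$gdd_bloom, shifted), 2)
  big <- gdd_params(5.9, 31.5, 1e6)
  expect_true(is.finite(gdd_objective(big, bds)))
})

test_that("the GA minimizes a convex toy objective deterministically within bounds", {
  bounds <- parameter_bounds(c(x = 0), c(x = 10))
  cfg <- quick_ga(seed = 9, pop = 30L, gens = 60L, patience = 60L)
  fit <- ga_optimize(function(p) (p[1] - 3)^2, bounds, cfg)
  expect_lt(abs(fit$par[["x"]] - 3), 1e-2)
  fit2 <- ga_optimize(function(p) (p[1] - 3)^2, bounds, cfg)
  expect_identical(fit, fit2)  # seeded determinism, bit-identical
  expect_true(all(diff(fit$fitness_trace) <= 0))  # never worsens

  expect_error(parameter_bounds(c(x = 1), c(x = 1)), "strictly below")
  expect_error(ga_optimize(function(p) NaN, bounds, cfg), "not finite")
  expect_error(ga_config(seed = 1, population_size = 2), "population_size")
})

test_that("GA results always stay inside the search box", {
  bounds <- parameter_bounds(c(a = -2, b = 5), c(a = 1, b = 6))
  set.seed(55)
  for (s in sample.int(10000, 5)) {
    fit <- ga_optimize(function(p) sin(7 * p[1]) * cos(3 * p[2]) + p[1]^2,
                       bounds, quick_ga(seed = s, gens = 15L))
    expect_true(all(fit$par >= bounds$lower & fit$par <= bounds$upper))
  }
})

test_that("LOOCV produces one fold per observation with honest statistics", {
  so <- make_toy_dataset()
  ds <- so$dataset
  # narrow box around the truth so the tiny GA budget suffices
  tight <- parameter_bounds(c(tc = 9, cr = -125), c(tc = 10, cr = -105))
  res <- loocv(ds, kind = "cac", bounds = tight,
               config = quick_ga(seed = 31, pop = 16L, gens = 12L))
  expect_s3_class(res, "loocv_result")
  expect_length(res$errors, nrow(ds$observations))
  expect_equal(res$mean, mean(res$errors))
  expect_equal(res$stdev, sd(res$errors))
  expect_lte(res$mean, 1)  # noise-free self-recovery
  expect_error(loocv(pheno_dataset(ds$observations[1:2, ], ds$seasons),
                     "cac", config = quick_ga(1)),
               "at least 3")
})

test_that("taylor statistics satisfy the Taylor identity and its special cases", {
  obs <- c(100, 110, 120, 140, 150, 135)
  ident <- taylor_stats(obs, obs)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$sd_ratio, 1)
  expect_equal(ident$centered_rmse_norm, 0)

  shifted <- taylor_stats(obs + 7, obs)   # bias-insensitive
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$sd_ratio, 1)
  expect_equal(shifted$centered_rmse_norm, 0)
  expect_equal(shifted$rmse, 7)           # plain rmse keeps the bias

  scaled <- taylor_stats(2 * (obs - mean(obs)) + mean(obs), obs)
  expect_equal(scaled$sd_ratio, 2)
  expect_equal(scaled$pearson_r, 1)

  set.seed(61)
  for (k in 1:25) {
    p <- rnorm(10); o <- rnorm(10)
    st <- taylor_stats(p, o)
    expect_lt(abs(st$centered_rmse_norm^2 -
                  (st$sd_ratio^2 + 1 - 2 * st$sd_ratio * st$pearson_r)),
              1e-9)
  }
  expect_error(taylor_stats(1:5, rep(3, 5)), "variance")
})

test_that("phenology summaries aggregate by cultivar and budbreak class", {
  means <- olive_phase_means()
  s <- summarize_phenology(means)
  pit <- s$class_diff[s$class_diff$phase == "pit_hardening", ]
  expect_equal(pit$mean_jday, 28)

  one <- summarize_phenology(means[1, ])
  expect_equal(one$by_cultivar$mean_jday, means$mean_jday[1])

  bad <- means; bad$class[2] <- "late-ish"
  expect_error(summarize_phenology(bad), "unknown cultivar class")
})
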