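# Seeded generator of Mediterranean-like daily weather and model-consistent
# phenological observations, so calibration and validation can be exercised
# end to end without any external data.

#' Describe a synthetic site climate
#'
#' A sinusoidal annual cycle with AR(1) day-to-day noise. The defaults
#' emulate a Mediterranean olive-growing site: annual mean 17 deg C,
#' annual half-amplitude 10 deg C (coldest around early February at
#' ~7 deg C, warmest in August at ~27 deg C), 8 deg C diurnal range,
#' moderately persistent daily anomalies.
#'
#' @param annual_mean Annual mean temperature, deg C.
#' @param annual_amplitude Half peak-to-trough amplitude of the annual
#'   cycle, deg C (> 0).
#' @param coldest_day Day of year of the temperature minimum.
#' @param diurnal_range `tmax - tmin`, deg C (> 0).
#' @param ar1_rho Lag-1 autocorrelation of daily anomalies, in [0, 1).
#' @param noise_sd Stationary standard deviation of the anomalies, deg C.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `site_climate`.
#' @export
site_climate <- function(annual_mean = 17, annual_amplitude = 10,
                         coldest_day = 36, diurnal_range = 8,
                         ar1_rho = 0.7, noise_sd = 2, seed = 1L) {
  stopifnot(annual_amplitude > 0, diurnal_range > 0,
            ar1_rho >= 0, ar1_rho < 1, noise_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(annual_mean = annual_mean,
                 annual_amplitude = annual_amplitude,
                 coldest_day = coldest_day, diurnal_range = diurnal_range,
                 ar1_rho = ar1_rho, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "site_climate")
}

#' Simulate daily weather for one site
#'
#' Daily mean cycle
#' `m(d) = annual_mean - annual_amplitude * cos(2 * pi * (d - coldest_day) / 365.25)`
#' (minimum at `coldest_day`), plus an AR(1) anomaly with stationary sd
#' `noise_sd`, applied identically to `tmin` and `tmax` so the diurnal
#' range -- and the `tmin <= tmax` invariant -- is preserved exactly.
#'
#' @param site A [site_climate()].
#' @param years Integer vector of calendar years to generate (whole years).
#' @param site_id Label for the emitted series.
#' @return A validated [weather_series()].
#' @export
simulate_weather <- function(site, years, site_id = "synthetic") {
  stopifnot(inherits(site, "site_climate"), length(years) >= 1L)
  years <- sort(as.integer(years))
  dates <- seq(as.Date(sprintf("%d-01-01", years[1L])),
               as.Date(sprintf("%d-12-31", years[length(years)])), by = "day")
  doy <- as.integer(format(dates, "%j"))
  m <- site$annual_mean -
    site$annual_amplitude * cos(2 * pi * (doy - site$coldest_day) / 365.25)
  n <- length(dates)
  e <- numeric(n)
  if (site$noise_sd > 0) {
    .with_seed(site$seed, {
      innov_sd <- site$noise_sd * sqrt(1 - site$ar1_rho^2)
      z <- stats::rnorm(n, sd = innov_sd)
      e[1L] <- stats::rnorm(1L, sd = site$noise_sd)
      for (t in 2:n) e[t] <- site$ar1_rho * e[t - 1L] + z[t]
    })
  }
  mid <- m + e
  weather_series(dates, mid - site$diurnal_range / 2,
                 mid + site$diurnal_range / 2,
                 site_id = site_id)
}

#' Simulate a network of sites along a thermal gradient
#'
#' One series per offset, shifting the base climate's annual mean (e.g.
#' `c(-2, 0, 2)` for a cool, a reference and a warm site, emulating the
#' ~14-19 deg C spread of Italian olive sites). Site `i` draws from
#' sub-seed `base$seed + i - 1` so networks are reproducible yet sites are
#' independent; a single zero offset reproduces `simulate_weather(base)`.
#'
#' @param base A [site_climate()].
#' @param offsets Numeric vector of annual-mean shifts, deg C.
#' @param years Years to generate.
#' @return A named list of [weather_series()], names `site1`, `site2`, ...
#' @export
simulate_site_network <- function(base, offsets, years) {
  stopifnot(inherits(base, "site_climate"), length(offsets) >= 1L)
  out <- vector("list", length(offsets))
  names(out) <- paste0("site", seq_along(offsets))
  for (i in seq_along(offsets)) {
    s <- base
    s$annual_mean <- base$annual_mean + offsets[i]
    s$seed <- base$seed + i - 1L
    out[[i]] <- simulate_weather(s, years, site_id = names(out)[i])
  }
  out
}

#' Simulate model-consistent phenological observations
#'
#' Runs the full prediction chain for every site and phenology year, then
#' adds rounded Gaussian day noise to each successful date (observations
#' are calendar days). Site-years where the model fails any requested
#' phase are dropped and counted, mirroring how unmet chilling/heating
#' requirements yield no phenological date. With `obs_noise_sd = 0` the
#' observations equal the forward predictions exactly.
#'
#' @param cv A [cultivar_params()] truth used by the forward model.
#' @param weather Named list of [weather_series()] (e.g. from
#'   [simulate_site_network()]), each covering every requested season.
#' @param years Phenology years to observe.
#' @param obs_noise_sd Observation noise sd in days (rounded to whole
#'   days).
#' @param seed Integer seed for the noise draws.
#' @param phases Phases to record.
#' @return An object of class `synthetic_observation_set`: list with
#'   `dataset` (a [pheno_dataset()]), `true_params`, `n_failed`,
#'   `obs_noise_sd` and `seed`. The dataset's `sprouting_jday` column
#'   carries the (noisy) observed sprouting day used as the forcing start.
#' @export
simulate_observations <- function(cv, weather, years, obs_noise_sd = 0,
                                  seed = 1L,
                                  phases = c("sprouting", "blooming",
                                             "pit_hardening")) {
  stopifnot(inherits(cv, "cultivar_params"), length(weather) >= 1L,
            obs_noise_sd >= 0)
  phases <- match.arg(phases, several.ok = TRUE)
  if (is.null(names(weather)))
    names(weather) <- paste0("site", seq_along(weather))
  seasons <- list()
  rows <- list()
  n_failed <- 0L
  .with_seed(as.integer(seed), {
    for (sid in names(weather)) {
      for (y in as.integer(years)) {
        season <- build_dormancy_season(weather[[sid]], y)
        chain <- predict_chain(season, cv)
        ok <- vapply(chain[phases], function(p) p$status == "success",
                     logical(1))
        if (!all(ok)) {
          n_failed <- n_failed + 1L
          next
        }
        key <- paste(sid, y, sep = ":")
        seasons[[key]] <- season
        noise <- function(jd)
          jd + round(stats::rnorm(1L, sd = obs_noise_sd))
        sprout_obs <- noise(chain$sprouting$jday)
        for (ph in phases) {
          jd <- if (ph == "sprouting") sprout_obs else noise(chain[[ph]]$jday)
          rows[[length(rows) + 1L]] <-
            data.frame(site = sid, cultivar = cv$cultivar, phase = ph,
                       year = y, jday = jd, sprouting_jday = sprout_obs)
        }
      }
    }
  })
  if (!length(rows))
    stop("every site-year failed a requirement; use warmer parameters ",
         "or a milder climate", call. = FALSE)
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  structure(list(dataset = pheno_dataset(obs, seasons), true_params = cv,
                 n_failed = n_failed, obs_noise_sd = obs_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_observation_set")
}

#' @export
print.synthetic_observation_set <- function(x, ...) {
  cat(sprintf(
    "synthetic observations: %d records (%d site-years dropped), noise sd %g d\n",
    nrow(x$dataset$observations), x$n_failed, x$obs_noise_sd))
  invisible(x)
}
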