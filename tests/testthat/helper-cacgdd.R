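# shared builders for the test suite; everything is generated in code

# constant-temperature weather over one Nov-Oct season plus margins
const_series <- function(tmin, tmax, from = "2001-01-01", to = "2002-12-31",
                         site_id = "const") {
  d <- seq(as.Date(from), as.Date(to), by = "day")
  weather_series(d, rep_len(tmin, length(d)), rep_len(tmax, length(d)),
                 site_id = site_id)
}

# season with piecewise-constant (tmin, tmax) blocks: lens sums to <= 365,
# remainder filled with the last block
block_season <- function(lens, tmins, tmaxs, year = 2002L) {
  d <- seq(as.Date(sprintf("%d-11-01", year - 1L)),
           as.Date(sprintf("%d-10-31", year)), by = "day")
  n <- length(d)
  tn <- rep(tmins[length(tmins)], n)
  tx <- rep(tmaxs[length(tmaxs)], n)
  at <- 1L
  for (b in seq_along(lens)) {
    span <- at:(at + lens[b] - 1L)
    tn[span] <- tmins[b]; tx[span] <- tmaxs[b]
    at <- at + lens[b]
  }
  build_dormancy_season(weather_series(d, tn, tx, site_id = "block"), year)
}

# small GA budget for unit tests
quick_ga <- function(seed, pop = 24L, gens = 30L, patience = 12L) {
  ga_config(population_size = pop, max_generations = gens,
            early_stop_patience = patience, seed = seed)
}

# a sinusoidal day-of-year climatology with given annual mean
toy_climatology <- function(annual_mean = 16, amplitude = 9,
                            diurnal_range = 8, coldest = 36) {
  doy <- 1:365
  m <- annual_mean - amplitude * cos(2 * pi * (doy - coldest) / 365.25)
  structure(data.frame(doy = doy, tmin = m - diurnal_range / 2,
                       tmax = m + diurnal_range / 2),
            source_years = NA_integer_, site_id = "toy",
            latitude = NA_real_, longitude = NA_real_,
            class = c("climatology_series", "data.frame"))
}

# climatology grid whose annual mean varies linearly with latitude
gradient_grid <- function(lats, lons, mean_at = function(lat) 19 - (lat - 35),
                          amplitude = 9, diurnal_range = 8) {
  dims <- c(length(lats), length(lons), 365L)
  tmin <- array(NA_real_, dims); tmax <- array(NA_real_, dims)
  doy <- 1:365
  cyc <- -amplitude * cos(2 * pi * (doy - 36) / 365.25)
  for (i in seq_along(lats)) {
    m <- mean_at(lats[i]) + cyc
    for (j in seq_along(lons)) {
      tmin[i, j, ] <- m - diurnal_range / 2
      tmax[i, j, ] <- m + diurnal_range / 2
    }
  }
  temperature_grid(lats, lons, tmin, tmax, 1:365)
}
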