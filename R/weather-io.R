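# Reading, validating and windowing daily temperature data: site series,
# dormancy seasons, day-of-year climatologies and regular lat-lon grids.

.validate_weather <- function(df, site_id) {
  if (anyNA(df$tmin) || anyNA(df$tmax))
    stop("missing tmin/tmax values in weather for ", site_id, call. = FALSE)
  bad <- which(df$tmin > df$tmax)
  if (length(bad))
    stop("tmin > tmax at row ", bad[1L], " (", format(df$date[bad[1L]]), ")",
         call. = FALSE)
  gaps <- which(diff(as.integer(df$date)) != 1L)
  if (length(gaps))
    stop("dates are not contiguous: first missing day is ",
         format(df$date[gaps[1L]] + 1L), call. = FALSE)
  invisible(df)
}

#' Construct a validated daily weather series
#'
#' A weather series is a data frame of contiguous calendar days with
#' columns `date`, `tmin`, `tmax`, `tmean` and site metadata in attributes.
#' When no measured mean is supplied, `tmean` is derived as
#' `(tmin + tmax) / 2` and the series is flagged accordingly.
#'
#' @param date `Date` vector (will be sorted; must be gap-free).
#' @param tmin,tmax Daily extremes, deg C.
#' @param tmean Optional measured daily mean, deg C.
#' @param site_id,latitude,longitude Site metadata.
#' @return A data frame of class `weather_series`.
#' @export
weather_series <- function(date, tmin, tmax, tmean = NULL,
                           site_id = "site", latitude = NA_real_,
                           longitude = NA_real_) {
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable dates in weather input", call. = FALSE)
  ord <- order(date)
  derived <- is.null(tmean)
  df <- data.frame(date = date[ord], tmin = as.numeric(tmin)[ord],
                   tmax = as.numeric(tmax)[ord])
  if (anyDuplicated(df$date))
    stop("duplicated dates in weather input", call. = FALSE)
  df$tmean <- if (derived) (df$tmin + df$tmax) / 2 else as.numeric(tmean)[ord]
  .validate_weather(df, site_id)
  if (!derived) {
    bad <- which(df$tmean < df$tmin | df$tmean > df$tmax)
    if (length(bad))
      stop("tmean outside [tmin, tmax] at row ", bad[1L], call. = FALSE)
  }
  structure(df, site_id = site_id, latitude = latitude, longitude = longitude,
            tmean_derived = derived,
            class = c("weather_series", "data.frame"))
}

#' Read a daily weather table
#'
#' Reads a delimited text table with header `date,tmin,tmax[,tmean]`
#' (ISO-8601 dates, temperatures in deg C) into a validated
#' [weather_series()]. Rows are sorted by date; gaps, unparseable dates and
#' `tmin > tmax` rows are errors.
#'
#' @param path Path to the CSV file.
#' @param site_id,latitude,longitude Site metadata attached to the series.
#' @param kelvin If `TRUE`, temperatures are converted from Kelvin.
#' @return A [weather_series()].
#' @export
read_daily_weather <- function(path, site_id = "site", latitude = NA_real_,
                               longitude = NA_real_, kelvin = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("weather table misses column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  shift <- if (kelvin) 273.15 else 0
  weather_series(df$date, df$tmin - shift, df$tmax - shift,
                 tmean = if ("tmean" %in% names(df)) df$tmean - shift,
                 site_id = site_id, latitude = latitude, longitude = longitude)
}

#' @rdname read_daily_weather
#' @param series A [weather_series()] to write.
#' @details `write_daily_weather()` writes temperatures with 17 significant
#'   digits so a write/read round trip reproduces the series exactly.
#' @export
write_daily_weather <- function(series, path) {
  stopifnot(inherits(series, "weather_series"))
  out <- data.frame(date = format(series$date),
                    tmin = sprintf("%.17g", series$tmin),
                    tmax = sprintf("%.17g", series$tmax))
  if (!isTRUE(attr(series, "tmean_derived")))
    out$tmean <- sprintf("%.17g", series$tmean)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cut one dormancy season out of a weather series
#'
#' The dormancy season of phenology year `Y` runs from 1 November of year
#' `Y - 1` through 31 October of year `Y` (365 days, or 366 when `Y` is a
#' leap year). All seasonal accumulation starts on its first day.
#'
#' @param series A [weather_series()].
#' @param phenology_year Integer year `Y`.
#' @return A data frame of class `dormancy_season` (also a
#'   `weather_series`) with attribute `phenology_year`.
#' @export
build_dormancy_season <- function(series, phenology_year) {
  stopifnot(inherits(series, "weather_series"),
            length(phenology_year) == 1L)
  phenology_year <- as.integer(phenology_year)
  from <- as.Date(sprintf("%d-11-01", phenology_year - 1L))
  to <- as.Date(sprintf("%d-10-31", phenology_year))
  if (series$date[1L] > from || series$date[nrow(series)] < to)
    stop(sprintf("series does not cover the %s .. %s season window",
                 format(from), format(to)), call. = FALSE)
  out <- series[series$date >= from & series$date <= to, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("site_id", "latitude", "longitude", "tmean_derived")] <-
    attributes(series)[c("site_id", "latitude", "longitude", "tmean_derived")]
  attr(out, "phenology_year") <- phenology_year
  class(out) <- c("dormancy_season", "weather_series", "data.frame")
  out
}

# day-of-year on a fixed 365-day calendar: Feb 29 is NA, later leap-year
# days shift back one so e.g. Mar 1 is always day 60.
.doy365 <- function(date) {
  doy <- as.integer(format(date, "%j"))
  leap <- format(date, "%m-%d") == "02-29"
  post <- !leap & doy > 59 & .is_leap(as.integer(format(date, "%Y")))
  doy[post] <- doy[post] - 1L
  doy[leap] <- NA_integer_
  doy
}

.is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Long-term day-of-year temperature climatology
#'
#' Averages `tmin` and `tmax` for every calendar day across the requested
#' years, dropping 29 February so the result always has exactly 365
#' entries.
#'
#' @param series A [weather_series()] covering every requested year fully.
#' @param years Integer vector of years to average (e.g. `1985:2015`).
#' @return A data frame of class `climatology_series` with columns `doy`,
#'   `tmin`, `tmax` and attribute `source_years`.
#' @export
build_climatology <- function(series, years) {
  stopifnot(inherits(series, "weather_series"), length(years) >= 1L)
  years <- sort(as.integer(years))
  from <- as.Date(sprintf("%d-01-01", years[1L]))
  to <- as.Date(sprintf("%d-12-31", years[length(years)]))
  if (series$date[1L] > from || series$date[nrow(series)] < to)
    stop(sprintf("series does not cover %s .. %s", format(from), format(to)),
         call. = FALSE)
  keep <- as.integer(format(series$date, "%Y")) %in% years
  sub <- series[keep, , drop = FALSE]
  doy <- .doy365(sub$date)
  ok <- !is.na(doy)
  tmin <- tapply(sub$tmin[ok], doy[ok], mean)
  tmax <- tapply(sub$tmax[ok], doy[ok], mean)
  out <- data.frame(doy = as.integer(names(tmin)),
                    tmin = as.numeric(tmin), tmax = as.numeric(tmax))
  out <- out[order(out$doy), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(nrow(out) == 365L)
  structure(out, source_years = years,
            site_id = attr(series, "site_id"),
            latitude = attr(series, "latitude"),
            longitude = attr(series, "longitude"),
            class = c("climatology_series", "data.frame"))
}

.check_axis <- function(x, what) {
  if (length(x) > 1L) {
    step <- diff(x)
    if (any(step <= 0))
      stop(what, " axis is not strictly increasing", call. = FALSE)
    if (max(step) - min(step) > 1e-6)
      stop(what, " axis has an irregular step", call. = FALSE)
  }
  invisible(x)
}

#' Construct a regular latitude-longitude temperature grid
#'
#' Holds per-cell daily temperatures on strictly regular axes. A
#' climatology grid carries one 365-day mean year per cell (`time` =
#' day-of-year 1..365); a series grid carries dated records (`time` =
#' `Date` vector, contiguous).
#'
#' @param latitudes,longitudes Regular, strictly increasing axes of cell
#'   centers (decimal degrees).
#' @param tmin,tmax Numeric arrays of dimension
#'   `c(n_lat, n_lon, n_time)`, deg C.
#' @param time Either `1:365` (climatology) or a contiguous `Date` vector.
#' @return An object of class `temperature_grid` with field `kind`
#'   (`"climatology"` or `"series"`).
#' @export
temperature_grid <- function(latitudes, longitudes, tmin, tmax, time) {
  .check_axis(latitudes, "latitude")
  .check_axis(longitudes, "longitude")
  dims <- c(length(latitudes), length(longitudes), length(time))
  if (!identical(dim(tmin), as.integer(dims)) ||
      !identical(dim(tmax), as.integer(dims)))
    stop("tmin/tmax arrays must have dim (n_lat, n_lon, n_time)",
         call. = FALSE)
  if (any(tmin > tmax))
    stop("tmin > tmax somewhere in the grid", call. = FALSE)
  if (inherits(time, "Date")) {
    if (any(diff(as.integer(time)) != 1L))
      stop("grid dates are not contiguous", call. = FALSE)
    kind <- "series"
  } else {
    if (!identical(as.integer(time), 1:365))
      stop("climatology grids must carry day-of-year 1..365", call. = FALSE)
    time <- 1:365
    kind <- "climatology"
  }
  structure(list(latitudes = as.numeric(latitudes),
                 longitudes = as.numeric(longitudes),
                 tmin = tmin, tmax = tmax, time = time, kind = kind),
            class = "temperature_grid")
}

#' @export
print.temperature_grid <- function(x, ...) {
  cat(sprintf("temperature_grid (%s): %d x %d cells, %d time steps\n",
              x$kind, length(x$latitudes), length(x$longitudes),
              length(x$time)))
  cat(sprintf("  lat %g..%g, lon %g..%g\n", min(x$latitudes),
              max(x$latitudes), min(x$longitudes), max(x$longitudes)))
  invisible(x)
}

#' Read or write a gridded temperature file
#'
#' Grids travel as long-format CSV with columns `lat,lon,<time>,tmin,tmax`,
#' where `<time>` is `doy` (1..365, a climatology grid) or `date`
#' (ISO-8601, a series grid). Axes must be regular; an optional window
#' restricts the cells kept on read.
#'
#' @param path CSV file path.
#' @param lat_range,lon_range Optional length-2 vectors subsetting the grid
#'   window on read.
#' @return `load_temperature_grid()` returns a [temperature_grid()];
#'   `write_temperature_grid()` invisibly returns `path`.
#' @export
load_temperature_grid <- function(path, lat_range = NULL, lon_range = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("doy", "date"), names(df))
  need <- c("lat", "lon", "tmin", "tmax")
  if (length(tcol) != 1L || length(setdiff(need, names(df))))
    stop("grid table needs columns lat, lon, doy|date, tmin, tmax",
         call. = FALSE)
  if (!is.null(lat_range)) df <- df[df$lat >= min(lat_range) &
                                    df$lat <= max(lat_range), ]
  if (!is.null(lon_range)) df <- df[df$lon >= min(lon_range) &
                                    df$lon <= max(lon_range), ]
  if (!nrow(df)) stop("no grid cells left after windowing", call. = FALSE)
  lats <- sort(unique(df$lat)); lons <- sort(unique(df$lon))
  time <- if (tcol == "doy") sort(unique(df$doy)) else
    sort(unique(as.Date(df$date)))
  dims <- c(length(lats), length(lons), length(time))
  if (nrow(df) != prod(dims))
    stop("grid table is not a complete lat x lon x time lattice",
         call. = FALSE)
  ilat <- match(df$lat, lats); ilon <- match(df$lon, lons)
  itime <- if (tcol == "doy") match(df$doy, time) else
    match(as.Date(df$date), time)
  tmin <- array(NA_real_, dims); tmax <- array(NA_real_, dims)
  idx <- cbind(ilat, ilon, itime)
  tmin[idx] <- df$tmin; tmax[idx] <- df$tmax
  temperature_grid(lats, lons, tmin, tmax, time)
}

#' @rdname load_temperature_grid
#' @param grid A [temperature_grid()] to write.
#' @export
write_temperature_grid <- function(grid, path) {
  stopifnot(inherits(grid, "temperature_grid"))
  dims <- dim(grid$tmin)
  idx <- expand.grid(ilat = seq_len(dims[1L]), ilon = seq_len(dims[2L]),
                     itime = seq_len(dims[3L]))
  out <- data.frame(lat = sprintf("%.17g", grid$latitudes[idx$ilat]),
                    lon = sprintf("%.17g", grid$longitudes[idx$ilon]))
  if (grid$kind == "climatology") out$doy <- grid$time[idx$itime]
  else out$date <- format(grid$time[idx$itime])
  out$tmin <- sprintf("%.17g", grid$tmin[as.matrix(idx)])
  out$tmax <- sprintf("%.17g", grid$tmax[as.matrix(idx)])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the series of the grid cell nearest a point
#'
#' Matches a point to the nearest cell center (ties broken toward the lower
#' axis index, i.e. south/west) and returns that cell as a site series:
#' a [weather_series()] for series grids, a `climatology_series` for
#' climatology grids. Points farther than half a grid step outside the axis
#' range are out of bounds.
#'
#' @param grid A [temperature_grid()].
#' @param latitude,longitude Point coordinates, decimal degrees.
#' @return A `weather_series` or `climatology_series`.
#' @export
extract_cell <- function(grid, latitude, longitude) {
  stopifnot(inherits(grid, "temperature_grid"))
  near <- function(axis, x, what) {
    step <- if (length(axis) > 1L) axis[2L] - axis[1L] else 0.1
    if (x < axis[1L] - step / 2 || x > axis[length(axis)] + step / 2)
      stop(what, " ", x, " is outside the grid bounds", call. = FALSE)
    d <- abs(axis - x)
    which(d <= min(d) + 1e-9)[1L]  # tie -> lower index
  }
  i <- near(grid$latitudes, latitude, "latitude")
  j <- near(grid$longitudes, longitude, "longitude")
  tmin <- grid$tmin[i, j, ]; tmax <- grid$tmax[i, j, ]
  id <- sprintf("cell_%g_%g", grid$latitudes[i], grid$longitudes[j])
  if (grid$kind == "series") {
    weather_series(grid$time, tmin, tmax, site_id = id,
                   latitude = grid$latitudes[i],
                   longitude = grid$longitudes[j])
  } else {
    structure(data.frame(doy = 1:365, tmin = tmin, tmax = tmax),
              source_years = NA_integer_, site_id = id,
              latitude = grid$latitudes[i], longitude = grid$longitudes[j],
              class = c("climatology_series", "data.frame"))
  }
}
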