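# Cell-by-cell projection of the combined model over gridded temperature
# climatologies, producing Julian-day rasters per phase with a
# requirement-not-met mask, plus class-difference maps and raster I/O.

# season ordering of a 365-entry day-of-year climatology: Nov 1 (doy 305)
# .. Dec 31, then Jan 1 .. Oct 31 (doy 304). Season index i maps to
# jday i - 61 as everywhere else.
.season_doy <- c(305:365, 1:304)

#' Assemble one mean-year dormancy season from a climatology
#'
#' Wraps a 365-day day-of-year climatology into a single synthetic
#' November-October season (a non-leap reference year is used for the
#' dates), the input the mean-year spatial projection feeds to the model.
#'
#' @param clim A `climatology_series` (see [build_climatology()]).
#' @return A [build_dormancy_season()] object.
#' @export
climatology_season <- function(clim) {
  stopifnot(inherits(clim, "climatology_series"))
  dates <- seq(as.Date("2001-11-01"), as.Date("2002-10-31"), by = "day")
  idx <- .season_doy
  series <- weather_series(dates, clim$tmin[idx], clim$tmax[idx],
                           site_id = attr(clim, "site_id") %||% "climatology",
                           latitude = attr(clim, "latitude"),
                           longitude = attr(clim, "longitude"))
  build_dormancy_season(series, 2002L)
}

.empty_raster <- function(grid, phase, cultivar) {
  vals <- matrix(NA_integer_, length(grid$latitudes), length(grid$longitudes))
  structure(list(latitudes = grid$latitudes, longitudes = grid$longitudes,
                 values = vals, mask = vals == vals,  # all NA -> filled below
                 phase = phase, cultivar = cultivar),
            class = "phenology_raster")
}

#' Project phenological dates over a temperature grid
#'
#' Runs the combined model in every grid cell and returns one Julian-day
#' raster per phase. For a climatology grid (the default mean-year mode),
#' each cell's 365-day mean year is wrapped into a single November-October
#' season and the chain is run once. For a multi-year series grid with
#' `mode = "per-year"`, the chain is run for every phenology year the grid
#' covers and the per-phase Julian days are averaged over the years in
#' which that phase succeeded.
#'
#' Cells where a phase's requirement is never met are masked for that phase
#' and every later phase (in per-year mode: cells with no successful year).
#'
#' @param grid A [temperature_grid()].
#' @param cv A [cultivar_params()] object.
#' @param mode `"mean-year"` (climatology grids) or `"per-year"` (series
#'   grids).
#' @return A named list of three `phenology_raster` objects (`sprouting`,
#'   `blooming`, `pit_hardening`), each with integer `values` (Julian day,
#'   `NA` where masked) and a logical `mask` (`TRUE` = requirement not
#'   met).
#' @export
project_grid <- function(grid, cv, mode = c("mean-year", "per-year")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "temperature_grid"), inherits(cv, "cultivar_params"))
  nlat <- length(grid$latitudes); nlon <- length(grid$longitudes)
  phases <- c("sprouting", "blooming", "pit_hardening")

  if (mode == "mean-year") {
    if (grid$kind != "climatology")
      stop("mean-year projection needs a climatology grid", call. = FALSE)
    ncell <- nlat * nlon
    # cells x 365 season matrices, vectorized case evaluation in one pass
    tn <- matrix(grid$tmin, ncell, 365L)[, .season_doy, drop = FALSE]
    tx <- matrix(grid$tmax, ncell, 365L)[, .season_doy, drop = FALSE]
    cc <- .cac_core(as.numeric(tn), as.numeric(tx), cv$cac$tc)
    cd <- matrix(cc$cd, ncell, 365L)
    ca <- matrix(cc$ca, ncell, 365L)
    gb <- matrix(.gdd_core(as.numeric(tn), as.numeric(tx),
                           cv$gdd_bloom$tb, cv$gdd_bloom$tx_base),
                 ncell, 365L)
    jd <- matrix(NA_integer_, ncell, 3L)
    for (cell in seq_len(ncell)) {
      s <- cumsum(cd[cell, ])
      release <- match(TRUE, s <= cv$cac$cr)
      if (is.na(release) || release >= 365L) next
      s2 <- s[release] + cumsum(ca[cell, (release + 1L):365L])
      hit <- match(TRUE, s2 >= 0)
      if (is.na(hit)) next
      sprout <- release + hit
      jd[cell, 1L] <- sprout - 61L
      if (sprout >= 365L) next
      g <- cumsum(gb[cell, (sprout + 1L):365L])
      hb <- match(TRUE, g >= cv$gdd_bloom$hr)
      if (!is.na(hb)) jd[cell, 2L] <- sprout + hb - 61L
      hp <- match(TRUE, g >= cv$gdd_pit$hr)
      if (!is.na(hp)) jd[cell, 3L] <- sprout + hp - 61L
    }
  } else {
    if (grid$kind != "series")
      stop("per-year projection needs a dated series grid", call. = FALSE)
    yrs <- sort(unique(as.integer(format(grid$time, "%Y"))))
    years <- yrs[-1L]  # first year only supplies November-December
    ncell <- nlat * nlon
    sums <- matrix(0, ncell, 3L); cnt <- matrix(0L, ncell, 3L)
    for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
      cellser <- weather_series(grid$time, grid$tmin[i, j, ],
                                grid$tmax[i, j, ])
      cell <- (j - 1L) * nlat + i
      for (y in years) {
        chain <- predict_chain(build_dormancy_season(cellser, y), cv)
        for (k in 1:3) {
          p <- chain[[k]]
          if (p$status == "success") {
            sums[cell, k] <- sums[cell, k] + p$jday
            cnt[cell, k] <- cnt[cell, k] + 1L
          }
        }
      }
    }
    jd <- matrix(NA_integer_, ncell, 3L)
    ok <- cnt > 0L
    jd[ok] <- as.integer(round(sums[ok] / cnt[ok]))
  }

  # a failed earlier phase masks every later one
  jd[is.na(jd[, 1L]), 2:3] <- NA_integer_
  jd[is.na(jd[, 2L]), 3L] <- NA_integer_
  out <- vector("list", 3L)
  names(out) <- phases
  for (k in 1:3) {
    r <- .empty_raster(grid, phases[k], cv$cultivar)
    r$values <- matrix(jd[, k], nlat, nlon)
    r$mask <- is.na(r$values)
    out[[k]] <- r
  }
  out
}

#' @export
print.phenology_raster <- function(x, ...) {
  cat(sprintf(
    "phenology_raster '%s' (%s): %d x %d cells, %d masked\n",
    x$phase, x$cultivar, length(x$latitudes), length(x$longitudes),
    sum(x$mask)))
  invisible(x)
}

#' Cell-wise difference between two phenology rasters
#'
#' `late - early` in days, on identical grids and phases; a cell masked in
#' either input is masked in the difference. Anti-symmetric by
#' construction.
#'
#' @param late,early `phenology_raster` objects on the same grid and phase.
#' @return An object of class `difference_raster`.
#' @export
difference_map <- function(late, early) {
  stopifnot(inherits(late, "phenology_raster"),
            inherits(early, "phenology_raster"))
  if (!isTRUE(all.equal(late$latitudes, early$latitudes)) ||
      !isTRUE(all.equal(late$longitudes, early$longitudes)))
    stop("rasters are on different grids", call. = FALSE)
  if (!identical(late$phase, early$phase))
    stop("rasters are for different phases", call. = FALSE)
  vals <- late$values - early$values
  structure(list(latitudes = late$latitudes, longitudes = late$longitudes,
                 values = vals, mask = is.na(vals), phase = late$phase,
                 cultivars = c(late = late$cultivar, early = early$cultivar)),
            class = "difference_raster")
}

#' Write or read a phenology raster
#'
#' Rasters travel as CSV with columns `lat,lon,jday`; masked cells carry
#' the declared fill value. Two comment header lines record the phase,
#' cultivar and fill value so `read_raster()` restores the object
#' losslessly (axes are written at full precision).
#'
#' @param raster A `phenology_raster` or `difference_raster`.
#' @param path Output file path.
#' @param fill Fill value written for masked cells.
#' @return `write_raster()` invisibly returns `path`; `read_raster()`
#'   returns the reconstructed raster object.
#' @export
write_raster <- function(raster, path, fill = -9999L) {
  stopifnot(inherits(raster, c("phenology_raster", "difference_raster")))
  cultivar <- if (inherits(raster, "phenology_raster")) raster$cultivar
  else paste(raster$cultivars, collapse = "-")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# class=%s phase=%s cultivar=%s", class(raster)[1L],
                       raster$phase, cultivar),
               sprintf("# fill=%d", fill)), con)
  idx <- expand.grid(i = seq_along(raster$latitudes),
                     j = seq_along(raster$longitudes))
  vals <- raster$values[as.matrix(idx)]
  vals[is.na(vals)] <- fill
  utils::write.csv(data.frame(lat = sprintf("%.17g", raster$latitudes[idx$i]),
                              lon = sprintf("%.17g", raster$longitudes[idx$j]),
                              jday = vals),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- regmatches(hdr[1L],
                     regexec("class=(\\S+) phase=(\\S+) cultivar=(\\S+)",
                             hdr[1L]))[[1L]]
  fill <- as.integer(sub("# fill=", "", hdr[2L]))
  df <- utils::read.csv(path, comment.char = "#")
  lats <- sort(unique(df$lat)); lons <- sort(unique(df$lon))
  vals <- matrix(NA_integer_, length(lats), length(lons))
  vals[cbind(match(df$lat, lats), match(df$lon, lons))] <- df$jday
  vals[vals == fill] <- NA_integer_
  if (meta[2L] == "difference_raster") {
    cvs <- strsplit(meta[4L], "-", fixed = TRUE)[[1L]]
    structure(list(latitudes = lats, longitudes = lons, values = vals,
                   mask = is.na(vals), phase = meta[3L],
                   cultivars = c(late = cvs[1L], early = cvs[2L])),
              class = "difference_raster")
  } else {
    structure(list(latitudes = lats, longitudes = lons, values = vals,
                   mask = is.na(vals), phase = meta[3L], cultivar = meta[4L]),
              class = "phenology_raster")
  }
}
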