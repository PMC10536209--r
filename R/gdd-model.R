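# Clamped growing-degree-day forcing accumulated from a dynamic start date
# (the sprouting day), and the full sprouting -> blooming -> pit-hardening
# prediction chain.

#' Daily growing degree days
#'
#' `GDD = (tx' + tn') / 2 - tb`, where `tn'` and `tx'` are the daily
#' minimum and maximum clamped into `[tb, tx_base]` before averaging.
#' The result is never negative.
#'
#' @param tmin,tmax Daily extremes, deg C (vectors recycle).
#' @param params A [gdd_params()] object.
#' @return Numeric vector of daily GDD units (>= 0).
#' @examples
#' daily_gdd(15, 25, gdd_params(5, 30, 100))  # 15
#' @export
daily_gdd <- function(tmin, tmax, params) {
  stopifnot(inherits(params, "gdd_params"))
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  bad <- which(tmin > tmax)
  if (length(bad)) stop("tmin > tmax at position ", bad[1L], call. = FALSE)
  .gdd_core(tmin, tmax, params$tb, params$tx_base)
}

.gdd_core <- function(tn, tx, tb, txb) {
  tn2 <- pmin(pmax(tn, tb), txb)
  tx2 <- pmin(pmax(tx, tb), txb)
  (tn2 + tx2) / 2 - tb
}

# cumulative GDD from the day after `start_idx`; returns fulfillment index
# into the season or NA.
.gdd_fulfill <- function(tn, tx, tb, txb, hr, start_idx) {
  n <- length(tn)
  if (start_idx >= n) return(list(idx = NA_integer_, gdd = numeric(0)))
  span <- (start_idx + 1L):n
  g <- .gdd_core(tn[span], tx[span], tb, txb)
  s <- cumsum(g)
  hit <- match(TRUE, s >= hr)
  list(idx = if (is.na(hit)) NA_integer_ else start_idx + hit,
       gdd = g, cumulative = s)
}

#' Accumulate growing degree days from a start day
#'
#' Accumulates clamped daily GDD over a dormancy season beginning the day
#' *after* `start` (the phase-event day itself contributes no forcing) and
#' records the first day on which the cumulative sum reaches the heating
#' requirement.
#'
#' @param season A [build_dormancy_season()] object.
#' @param start Start day: a `Date` inside the season window, or an integer
#'   Julian day of the phenology year.
#' @param params A [gdd_params()] object.
#' @return A `gdd_trajectory`: data frame with `date`, `gdd` and
#'   `cumulative` for every day after `start`, with attribute
#'   `fulfillment_day` (`Date` or `NA`).
#' @export
accumulate_gdd <- function(season, start, params) {
  stopifnot(inherits(season, "dormancy_season"), inherits(params, "gdd_params"))
  year <- attr(season, "phenology_year")
  if (!inherits(start, "Date")) {
    stopifnot(is.numeric(start), length(start) == 1L)
    start <- as.Date(sprintf("%d-01-01", year)) + (as.integer(start) - 1L)
  }
  idx <- match(start, season$date)
  if (is.na(idx))
    stop("`start` (", format(start), ") is outside the season window",
         call. = FALSE)
  ful <- .gdd_fulfill(season$tmin, season$tmax, params$tb, params$tx_base,
                      params$hr, idx)
  n <- nrow(season)
  span <- if (idx < n) (idx + 1L):n else integer(0)
  out <- data.frame(date = season$date[span], gdd = ful$gdd,
                    cumulative = if (length(span)) ful$cumulative else numeric(0))
  attr(out, "fulfillment_day") <-
    if (is.na(ful$idx)) as.Date(NA) else season$date[ful$idx]
  attr(out, "start") <- start
  attr(out, "params") <- params
  class(out) <- c("gdd_trajectory", "data.frame")
  out
}

#' Predict one forced phenological phase
#'
#' Runs [accumulate_gdd()] and wraps the fulfillment day as a phase
#' prediction (requirement-not-met when the heating requirement is never
#' reached by 31 October).
#'
#' @inheritParams accumulate_gdd
#' @param phase Label for the predicted phase, e.g. `"blooming"`.
#' @return A `phase_prediction`.
#' @export
predict_phase_date <- function(season, start, params, phase = "blooming") {
  traj <- accumulate_gdd(season, start, params)
  .phase_prediction(attr(traj, "fulfillment_day"),
                    attr(season, "phenology_year"), phase)
}

#' Predict sprouting, blooming and pit hardening for one season
#'
#' The full combined model: sprouting from the sequential chill/anti-chill
#' accumulation (or from a supplied observed sprouting date, as during
#' forcing-model calibration), then blooming and pit hardening each forced
#' with their own heating requirement, both accumulated from the sprouting
#' date (not chained bloom-to-pit). A sprouting failure propagates: all
#' downstream phases fail.
#'
#' @param season A [build_dormancy_season()] object.
#' @param cv A [cultivar_params()] object.
#' @param start_override Optional observed sprouting day (`Date` or Julian
#'   day) replacing the modelled sprouting date.
#' @return A `phenology_chain`: list with elements `sprouting`, `blooming`
#'   and `pit_hardening`, each a `phase_prediction`.
#' @export
predict_chain <- function(season, cv, start_override = NULL) {
  stopifnot(inherits(season, "dormancy_season"), inherits(cv, "cultivar_params"))
  year <- attr(season, "phenology_year")
  if (is.null(start_override)) {
    sprout <- predict_sprouting(season, cv$cac)
  } else {
    start <- start_override
    if (!inherits(start, "Date"))
      start <- as.Date(sprintf("%d-01-01", year)) + (as.integer(start) - 1L)
    sprout <- .phase_prediction(start, year, "sprouting")
  }
  if (sprout$status != "success") {
    chain <- list(sprouting = sprout,
                  blooming = .phase_prediction(as.Date(NA), year, "blooming"),
                  pit_hardening = .phase_prediction(as.Date(NA), year,
                                                    "pit_hardening"))
  } else {
    chain <- list(
      sprouting = sprout,
      blooming = predict_phase_date(season, sprout$date, cv$gdd_bloom,
                                    "blooming"),
      pit_hardening = predict_phase_date(season, sprout$date, cv$gdd_pit,
                                         "pit_hardening"))
  }
  structure(chain, phenology_year = year, cultivar = cv$cultivar,
            class = "phenology_chain")
}

#' @export
print.phenology_chain <- function(x, ...) {
  cat(sprintf("Phenology chain, %s, year %d\n", attr(x, "cultivar"),
              attr(x, "phenology_year")))
  for (p in x) {
    cat("  "); print(p)
  }
  invisible(x)
}
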