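# Chill / anti-chill days model: six-case single-triangle formulas and the
# sequential endo-/eco-dormancy accumulation that yields the sprouting date.

# Case selection. Exhaustive and mutually exclusive for any tn <= tx and
# tc > 0; the all-frozen case is taken as tn <= tx < 0 so degenerate days
# (tn == tx) still fall in exactly one case.
.cac_case <- function(tn, tx, tc) {
  case <- integer(length(tn))
  frozen <- tx < 0
  case[frozen] <- 6L
  cross <- !frozen & tn < 0
  case[cross & tx <= tc] <- 4L
  case[cross & tx > tc] <- 5L
  warm <- !frozen & tn >= 0
  case[warm & tn >= tc] <- 1L
  case[warm & tn < tc & tx <= tc] <- 3L
  case[warm & tn < tc & tx > tc] <- 2L
  case
}

# Fast internal kernel; returns plain vectors. `tm` defaults to the
# symmetric mean, which is the value consistent with the triangle geometry.
.cac_core <- function(tn, tx, tc, tm = NULL) {
  if (is.null(tm)) tm <- (tn + tx) / 2
  case <- .cac_case(tn, tx, tc)
  w <- tx - tn
  cd <- numeric(length(tn))
  ca <- numeric(length(tn))

  # area of the triangle above tc, by limit 0 when the triangle is flat
  above <- case == 2L | case == 5L
  a <- numeric(length(tn))
  pos <- above & w > 0
  a[pos] <- (tx[pos] - tc)^2 / (2 * w[pos])

  i <- case == 1L
  ca[i] <- tm[i] - tc
  i <- case == 2L
  cd[i] <- -((tm[i] - tn[i]) - a[i]); ca[i] <- a[i]
  i <- case == 3L
  cd[i] <- -(tm[i] - tn[i])
  i <- case == 4L & w > 0
  cd[i] <- -tx[i]^2 / (2 * w[i])
  i <- case == 5L
  cd[i] <- -(tx[i]^2 - (tx[i] - tc)^2) / (2 * w[i]); ca[i] <- a[i]
  list(cd = cd, ca = ca, case = case)
}

#' Daily chill and anti-chill units
#'
#' Computes the chill days (`cd`, always <= 0) and anti-chill days (`ca`,
#' always >= 0) produced by one day with minimum temperature `tmin` and
#' maximum `tmax`, given the threshold temperature `tc`. The day is modelled
#' as an idealized triangle rising from `tmin` to `tmax` and back; the six
#' closed-form cases are the clipped areas of that triangle between 0 degC
#' and `tc` (chill) and above `tc` (anti-chill):
#'
#' \describe{
#'   \item{1. `0 <= tc <= tn <= tx`}{`cd = 0`, `ca = tm - tc`}
#'   \item{2. `0 <= tn <= tc < tx`}{`cd = -((tm - tn) - (tx - tc)^2 / (2 (tx - tn)))`,
#'     `ca = (tx - tc)^2 / (2 (tx - tn))`}
#'   \item{3. `0 <= tn <= tx <= tc`}{`cd = -(tm - tn)`, `ca = 0`}
#'   \item{4. `tn < 0 <= tx <= tc`}{`cd = -tx^2 / (2 (tx - tn))`, `ca = 0`}
#'   \item{5. `tn < 0 < tc < tx`}{`cd = -(tx^2 - (tx - tc)^2) / (2 (tx - tn))`,
#'     `ca = (tx - tc)^2 / (2 (tx - tn))`}
#'   \item{6. `tn <= tx < 0 < tc`}{`cd = 0`, `ca = 0`}
#' }
#'
#' where `tm = (tmin + tmax) / 2` unless a measured daily mean is supplied,
#' in which case it replaces `tm` in cases 1-3 only (the quadratic terms are
#' pure triangle areas and always use the extremes). Degenerate flat days
#' (`tmin == tmax`) take the limiting value 0 for every quadratic term.
#'
#' @param tmin,tmax Daily minimum and maximum temperature, deg C. Vectors
#'   are accepted and recycled against each other.
#' @param tc Threshold temperature, deg C (scalar, positive).
#' @param tmean Optional measured daily mean temperature used in cases 1-3
#'   instead of the symmetric mean.
#' @return A data frame with columns `cd` (chill units, <= 0), `ca`
#'   (anti-chill units, >= 0) and `case` (1-6).
#' @seealso [triangle_oracle()] for the numeric-integration reference,
#'   [accumulate_cac()] for the seasonal accumulation.
#' @examples
#' chill_anti_chill(2, 12, tc = 10)   # case 2: cd = -4.8, ca = 0.2
#' chill_anti_chill(-8, -2, tc = 10)  # frozen day: cd = 0, ca = 0
#' @export
chill_anti_chill <- function(tmin, tmax, tc, tmean = NULL) {
  stopifnot(is.numeric(tmin), is.numeric(tmax),
            is.numeric(tc), length(tc) == 1L, is.finite(tc))
  if (tc <= 0) stop("`tc` must be positive", call. = FALSE)
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  bad <- which(tmin > tmax)
  if (length(bad))
    stop("tmin > tmax at position ", bad[1L], call. = FALSE)
  tm <- NULL
  if (!is.null(tmean)) {
    tm <- rep_len(tmean, n)
    if (any(tm < tmin | tm > tmax))
      stop("`tmean` must lie within [tmin, tmax]", call. = FALSE)
  }
  res <- .cac_core(tmin, tmax, tc, tm)
  data.frame(cd = res$cd, ca = res$ca, case = res$case)
}

#' Numeric-integration oracle for the daily chill computation
#'
#' Integrates the idealized unit-day triangle temperature curve (rising
#' linearly from `tmin` to `tmax` over the first half day, falling back over
#' the second) with a midpoint rule, and reads the chill and anti-chill
#' units off the clipped areas: `ca` is the area above `tc`, `cd` minus the
#' area between `max(tmin, 0)` and `tc`. It is deliberately independent of
#' the closed forms in [chill_anti_chill()] and exists to cross-check them.
#'
#' @param tmin,tmax Daily extremes, deg C (scalars, `tmin <= tmax`).
#' @param tc Threshold temperature, deg C (positive).
#' @param n_steps Number of integration steps (>= 1000).
#' @return A one-row data frame with `cd`, `ca` and the `case` index.
#' @export
triangle_oracle <- function(tmin, tmax, tc, n_steps = 10000L) {
  stopifnot(length(tmin) == 1L, length(tmax) == 1L, length(tc) == 1L,
            is.finite(tmin), is.finite(tmax), is.finite(tc))
  if (tmin > tmax) stop("tmin > tmax", call. = FALSE)
  if (tc <= 0) stop("`tc` must be positive", call. = FALSE)
  if (n_steps < 1000L) stop("`n_steps` must be at least 1000", call. = FALSE)
  t <- (seq_len(n_steps) - 0.5) / n_steps
  temp <- ifelse(t <= 0.5,
                 tmin + (tmax - tmin) * t / 0.5,
                 tmax - (tmax - tmin) * (t - 0.5) / 0.5)
  ca <- mean(pmax(0, temp - tc))
  cd <- -mean(pmax(0, pmin(temp, tc) - pmax(tmin, 0)))
  data.frame(cd = cd, ca = ca, case = .cac_case(tmin, tmax, tc))
}

# Sequential accumulation on plain vectors. Phase 1 sums only chill days
# from the first season day until the running sum first reaches `cr`;
# phase 2 sums only anti-chill days from the next day until the sum first
# returns to zero. Returns indices into the season (NA when never reached).
.cac_accumulate <- function(tn, tx, tc, cr, tm = NULL) {
  res <- .cac_core(tn, tx, tc, tm)
  n <- length(tn)
  s <- cumsum(res$cd)
  release <- match(TRUE, s <= cr)
  sprout <- NA_integer_
  phase <- rep(1L, n)
  if (!is.na(release) && release < n) {
    idx2 <- (release + 1L):n
    phase[idx2] <- 2L
    s2 <- s[release] + cumsum(res$ca[idx2])
    s[idx2] <- s2
    hit <- match(TRUE, s2 >= 0)
    if (!is.na(hit)) sprout <- release + hit
  } else if (!is.na(release) && release == n) {
    # released on the last day: no forcing days remain
  } else {
    release <- NA_integer_
  }
  list(cd = res$cd, ca = res$ca, case = res$case, cumulative = s,
       phase = phase, release = release, sprout = sprout)
}

#' Accumulate chill and anti-chill units over a dormancy season
#'
#' Runs the sequential dormancy model over a November-October season.
#' Starting from zero on 1 November, only chill days are added until the
#' running sum first reaches the chilling requirement `cr` (endo-dormancy
#' release; anti-chill units are ignored in this phase). From the following
#' day only anti-chill days are added until the sum first climbs back to
#' zero, the predicted sprouting day. Either transition may never occur
#' within the season, in which case the corresponding day is `NA`.
#'
#' @param season A [build_dormancy_season()] object.
#' @param params A [cac_params()] object.
#' @param use_supplied_tmean If `TRUE` and the season carries measured daily
#'   means, those replace the symmetric mean in cases 1-3.
#' @return A `cac_trajectory`: a data frame with columns `date`, `cd`, `ca`,
#'   `cumulative` and `phase` (1 endo-, 2 eco-dormancy), with attributes
#'   `endo_release_day` and `sprouting_day` (`Date` or `NA`).
#' @export
accumulate_cac <- function(season, params, use_supplied_tmean = FALSE) {
  stopifnot(inherits(season, "dormancy_season"), inherits(params, "cac_params"))
  tm <- NULL
  if (use_supplied_tmean && !isTRUE(attr(season, "tmean_derived")))
    tm <- season$tmean
  acc <- .cac_accumulate(season$tmin, season$tmax, params$tc, params$cr, tm)
  out <- data.frame(date = season$date, cd = acc$cd, ca = acc$ca,
                    cumulative = acc$cumulative, phase = acc$phase)
  attr(out, "endo_release_day") <-
    if (is.na(acc$release)) as.Date(NA) else season$date[acc$release]
  attr(out, "sprouting_day") <-
    if (is.na(acc$sprout)) as.Date(NA) else season$date[acc$sprout]
  attr(out, "params") <- params
  class(out) <- c("cac_trajectory", "data.frame")
  out
}

#' Predict the sprouting date of one season
#'
#' Thin wrapper over [accumulate_cac()] returning a phase prediction: the
#' Julian day (within the phenology year, so days in November/December of
#' the previous calendar year come out zero or negative) of the first day
#' on which the accumulated sum returns to zero, or a requirement-not-met
#' failure when either the chilling or the balancing forcing never
#' completes by 31 October.
#'
#' @inheritParams accumulate_cac
#' @return A `phase_prediction` with fields `status` (`"success"` or
#'   `"requirement-not-met"`), `jday`, `date` and `phase`.
#' @export
predict_sprouting <- function(season, params, use_supplied_tmean = FALSE) {
  traj <- accumulate_cac(season, params, use_supplied_tmean)
  day <- attr(traj, "sprouting_day")
  .phase_prediction(day, attr(season, "phenology_year"), "sprouting")
}

# jday within the phenology year: 1 = Jan 1 of Y; Nov/Dec of Y-1 map to
# zero/negative values so the season index stays affine in jday.
.jday <- function(date, phenology_year) {
  as.integer(date - as.Date(sprintf("%d-01-01", phenology_year))) + 1L
}

.phase_prediction <- function(date, phenology_year, phase) {
  if (is.na(date)) {
    structure(list(status = "requirement-not-met", jday = NA_integer_,
                   date = as.Date(NA), phase = phase),
              class = "phase_prediction")
  } else {
    structure(list(status = "success", jday = .jday(date, phenology_year),
                   date = date, phase = phase),
              class = "phase_prediction")
  }
}

#' @export
print.phase_prediction <- function(x, ...) {
  if (x$status == "success")
    cat(sprintf("%s: JDay %d (%s)\n", x$phase, x$jday, format(x$date)))
  else
    cat(sprintf("%s: requirement not met\n", x$phase))
  invisible(x)
}

#' Export a trajectory to CSV
#'
#' Writes the per-day columns of a chill or GDD trajectory (date, daily
#' units, cumulative sum, phase) for external plotting.
#'
#' @param traj A `cac_trajectory` or `gdd_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, c("cac_trajectory", "gdd_trajectory")))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
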