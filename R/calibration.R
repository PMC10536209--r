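# Objective functions, calibration wrappers, leave-one-out cross-validation
# and evaluation statistics.

#' Root mean square error
#'
#' @param predicted,observed Numeric vectors of equal nonzero length
#'   (Julian days).
#' @return RMSE in days.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(predicted))
    stop("`predicted` and `observed` must have equal nonzero length",
         call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Bundle phenological observations with their seasons
#'
#' Pairs an observation table (columns `site`, `cultivar`, `phase`, `year`,
#' `jday`, optionally `sprouting_jday`) with the dormancy seasons the model
#' runs on. Seasons are keyed `"<site>:<year>"`; every observation must
#' have a matching season.
#'
#' @param observations Data frame of phenological observations.
#' @param seasons Named list of [build_dormancy_season()] objects, keyed
#'   `"<site>:<year>"`.
#' @return An object of class `pheno_dataset`.
#' @export
pheno_dataset <- function(observations, seasons) {
  need <- c("site", "cultivar", "phase", "year", "jday")
  missing <- setdiff(need, names(observations))
  if (length(missing))
    stop("observations miss column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(observations$jday < -61 | observations$jday > 366))
    stop("`jday` outside the phenology-year range", call. = FALSE)
  key <- paste(observations$site, observations$year, sep = ":")
  absent <- setdiff(unique(key), names(seasons))
  if (length(absent))
    stop("no season for observation key(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  structure(list(observations = observations, seasons = seasons),
            class = "pheno_dataset")
}

#' @export
print.pheno_dataset <- function(x, ...) {
  cat(sprintf("pheno_dataset: %d observations, %d seasons\n",
              nrow(x$observations), length(x$seasons)))
  invisible(x)
}

# Pre-extract plain vectors per observation row so objective evaluations
# inside the GA avoid data-frame overhead. `last_jday` is the Oct 31 jday
# used as the failure penalty.
.prep_rows <- function(dataset, rows) {
  obs <- dataset$observations[rows, , drop = FALSE]
  key <- paste(obs$site, obs$year, sep = ":")
  lapply(seq_len(nrow(obs)), function(i) {
    season <- dataset$seasons[[key[i]]]
    n <- nrow(season)
    list(tn = season$tmin, tx = season$tmax, n = n,
         last_jday = n - 61L,  # season index i maps to jday i - 61
         jday = obs$jday[i],
         sprout_jday = if ("sprouting_jday" %in% names(obs))
           obs$sprouting_jday[i] else NA_real_)
  })
}

.predict_sprout_jdays <- function(prep, tc, cr) {
  vapply(prep, function(p) {
    acc <- .cac_accumulate(p$tn, p$tx, tc, cr)
    if (is.na(acc$sprout)) p$last_jday else acc$sprout - 61L
  }, numeric(1))
}

.predict_gdd_jdays <- function(prep, tb, txb, hr) {
  vapply(prep, function(p) {
    start_idx <- as.integer(p$sprout_jday) + 61L
    if (is.na(start_idx) || start_idx < 1L || start_idx > p$n)
      stop("observation lacks a usable `sprouting_jday` start", call. = FALSE)
    ful <- .gdd_fulfill(p$tn, p$tx, tb, txb, hr, start_idx)
    if (is.na(ful$idx)) p$last_jday else ful$idx - 61L
  }, numeric(1))
}

#' Calibration objectives: RMSE of predicted vs observed dates
#'
#' `cac_objective()` scores chill-model parameters by the RMSE between
#' predicted and observed sprouting Julian days over every observation in
#' the dataset; `gdd_objective()` scores forcing parameters analogously,
#' starting the accumulation from each observation's recorded
#' `sprouting_jday`. Seasons where the requirement is never met substitute
#' the last season day (31 October) as a finite penalty, which keeps the
#' objective informative for the optimizer.
#'
#' @param params A [cac_params()] (resp. [gdd_params()]) object.
#' @param dataset A [pheno_dataset()]; for `cac_objective()` the `jday`
#'   column holds observed sprouting days, for `gdd_objective()` it holds
#'   the forced phase (blooming or pit hardening) and `sprouting_jday` the
#'   per-record start.
#' @return RMSE in days.
#' @export
cac_objective <- function(params, dataset) {
  stopifnot(inherits(params, "cac_params"), inherits(dataset, "pheno_dataset"))
  prep <- .prep_rows(dataset, seq_len(nrow(dataset$observations)))
  rmse(.predict_sprout_jdays(prep, params$tc, params$cr),
       vapply(prep, `[[`, numeric(1), "jday"))
}

#' @rdname cac_objective
#' @export
gdd_objective <- function(params, dataset) {
  stopifnot(inherits(params, "gdd_params"), inherits(dataset, "pheno_dataset"))
  prep <- .prep_rows(dataset, seq_len(nrow(dataset$observations)))
  rmse(.predict_gdd_jdays(prep, params$tb, params$tx_base, params$hr),
       vapply(prep, `[[`, numeric(1), "jday"))
}

#' Calibrate model parameters against observations
#'
#' Wraps [ga_optimize()] around the corresponding objective.
#' `calibrate_cac()` searches (Tc, Cr) against observed sprouting days;
#' `calibrate_gdd()` searches (Tb, Tx.base, Hr) against one forced phase,
#' accumulating from each record's observed sprouting day.
#'
#' @param dataset A [pheno_dataset()] (see [cac_objective()] for the
#'   expected columns).
#' @param bounds A [parameter_bounds()]; defaults to the published search
#'   boxes [cac_bounds()] / [gdd_bounds()].
#' @param config A [ga_config()].
#' @return A `calibration_result` whose `best_params` element is a
#'   [cac_params()] (resp. [gdd_params()]) object.
#' @export
calibrate_cac <- function(dataset, bounds = cac_bounds(), config) {
  stopifnot(inherits(dataset, "pheno_dataset"))
  prep <- .prep_rows(dataset, seq_len(nrow(dataset$observations)))
  obs <- vapply(prep, `[[`, numeric(1), "jday")
  objective <- function(par)
    rmse(.predict_sprout_jdays(prep, par[1L], par[2L]), obs)
  res <- ga_optimize(objective, bounds, config)
  res$best_params <- cac_params(res$par[["tc"]], res$par[["cr"]])
  res
}

#' @rdname calibrate_cac
#' @export
calibrate_gdd <- function(dataset, bounds = gdd_bounds(), config) {
  stopifnot(inherits(dataset, "pheno_dataset"))
  prep <- .prep_rows(dataset, seq_len(nrow(dataset$observations)))
  obs <- vapply(prep, `[[`, numeric(1), "jday")
  objective <- function(par)
    rmse(.predict_gdd_jdays(prep, par[1L], par[2L], par[3L]), obs)
  res <- ga_optimize(objective, bounds, config)
  res$best_params <- gdd_params(res$par[["tb"]], res$par[["tx_base"]],
                                res$par[["hr"]])
  res
}

#' Leave-one-out cross-validation
#'
#' For each observation in turn, calibrates the chosen model on all
#' remaining observations and records the absolute error (in days, i.e. the
#' single-observation RMSE) of the prediction for the held-out record.
#'
#' Model kinds: `"cac"` calibrates the chill model on sprouting
#' observations and predicts the held-out sprouting day; `"gdd"` calibrates
#' the forcing model on one phase (starting each record at its observed
#' `sprouting_jday`); `"chain"` calibrates both and predicts the held-out
#' forced phase from the *modelled* sprouting date, exercising the full
#' chain.
#'
#' @param dataset A [pheno_dataset()] with at least 3 observations of the
#'   relevant phase.
#' @param kind `"cac"`, `"gdd"` or `"chain"`.
#' @param bounds A [parameter_bounds()] for the calibrated model (for
#'   `"chain"`, a list with elements `cac` and `gdd`).
#' @param config A [ga_config()]; fold `f` runs with seed
#'   `config$seed + f` so folds are independent but reproducible.
#' @return An object of class `loocv_result`: per-fold absolute `errors`
#'   (days), their `mean` and `stdev`, and `n`.
#' @export
loocv <- function(dataset, kind = c("cac", "gdd", "chain"), bounds = NULL,
                  config) {
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "pheno_dataset"), inherits(config, "ga_config"))
  obs <- dataset$observations
  n <- nrow(obs)
  if (n < 3L) stop("LOOCV needs at least 3 observations", call. = FALSE)
  errors <- numeric(n)
  for (f in seq_len(n)) {
    train <- pheno_dataset(obs[-f, , drop = FALSE], dataset$seasons)
    test_prep <- .prep_rows(dataset, f)
    cfg <- config
    cfg$seed <- config$seed + f
    if (kind == "cac") {
      fit <- calibrate_cac(train, bounds %||% cac_bounds(), cfg)
      pred <- .predict_sprout_jdays(test_prep, fit$par[["tc"]],
                                    fit$par[["cr"]])
    } else if (kind == "gdd") {
      fit <- calibrate_gdd(train, bounds %||% gdd_bounds(), cfg)
      pred <- .predict_gdd_jdays(test_prep, fit$par[["tb"]],
                                 fit$par[["tx_base"]], fit$par[["hr"]])
    } else {
      if (!"sprouting_jday" %in% names(obs))
        stop("`chain` LOOCV needs a `sprouting_jday` column", call. = FALSE)
      sprout_train <- obs[-f, , drop = FALSE]
      sprout_train$jday <- sprout_train$sprouting_jday
      fit_cac <- calibrate_cac(pheno_dataset(sprout_train, dataset$seasons),
                               (bounds$cac) %||% cac_bounds(), cfg)
      cfg2 <- cfg; cfg2$seed <- cfg$seed + n
      fit_gdd <- calibrate_gdd(train, (bounds$gdd) %||% gdd_bounds(), cfg2)
      sp <- .predict_sprout_jdays(test_prep, fit_cac$par[["tc"]],
                                  fit_cac$par[["cr"]])
      test_prep[[1L]]$sprout_jday <- sp
      pred <- .predict_gdd_jdays(test_prep, fit_gdd$par[["tb"]],
                                 fit_gdd$par[["tx_base"]],
                                 fit_gdd$par[["hr"]])
    }
    errors[f] <- abs(pred - test_prep[[1L]]$jday)
  }
  structure(list(errors = errors, mean = mean(errors),
                 stdev = stats::sd(errors), n = n),
            class = "loocv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV over %d folds: mean %.2f days, sd %.2f days\n",
              x$n, x$mean, x$stdev))
  invisible(x)
}

#' Taylor-diagram statistics
#'
#' The quantities a normalized Taylor diagram displays for a model against
#' observations: Pearson correlation, the ratio of standard deviations, and
#' the centered (bias-removed) RMSE normalized by the observed standard
#' deviation. They satisfy the Taylor identity
#' `crmse^2 = sd_ratio^2 + 1 - 2 * sd_ratio * r`.
#'
#' @param predicted,observed Numeric vectors of equal length >= 3;
#'   `observed` must have positive variance.
#' @return An object of class `eval_stats`: list with `rmse` (plain, days),
#'   `pearson_r`, `sd_ratio` and `centered_rmse_norm`.
#' @export
taylor_stats <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 3L)
    stop("need equal lengths >= 3", call. = FALSE)
  so <- stats::sd(observed)
  if (!is.finite(so) || so <= 0)
    stop("observed values have zero variance", call. = FALSE)
  sp <- stats::sd(predicted)
  r <- if (sp > 0) stats::cor(predicted, observed) else 0
  dp <- predicted - mean(predicted)
  do <- observed - mean(observed)
  crmse <- sqrt(sum((dp - do)^2) / (length(observed) - 1L))
  structure(list(rmse = rmse(predicted, observed), pearson_r = r,
                 sd_ratio = sp / so, centered_rmse_norm = crmse / so),
            class = "eval_stats")
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf(
    "RMSE %.2f days | r %.3f | sd ratio %.3f | centered RMSE/sd(obs) %.3f\n",
    x$rmse, x$pearson_r, x$sd_ratio, x$centered_rmse_norm))
  invisible(x)
}

#' Summarize phenology tables by cultivar and budbreak class
#'
#' Works on any table carrying `cultivar` and `class` columns plus numeric
#' value columns -- raw observations (value `jday`, with a `phase` column),
#' the packaged mean-date table or the packaged parameter table. Returns
#' per-cultivar means, per-class means and the class contrast
#' (mid-late minus early) for every numeric column, within each phase when
#' a `phase` column is present.
#'
#' @param df Data frame with `cultivar`, `class` and numeric value columns
#'   (`year` and `site` are ignored).
#' @return A list with data frames `by_cultivar`, `by_class` and
#'   `class_diff`.
#' @export
summarize_phenology <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) >= 1L)
  if (!all(c("cultivar", "class") %in% names(df)))
    stop("table needs `cultivar` and `class` columns", call. = FALSE)
  if (anyNA(df$class) || !all(df$class %in% c("early", "mid-late")))
    stop("unknown cultivar class (expected 'early' or 'mid-late')",
         call. = FALSE)
  vals <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                  c("year", "jday_sd"))
  vals <- setdiff(vals, "sprouting_jday")
  if (!length(vals)) stop("no numeric value columns", call. = FALSE)
  keys <- intersect(c("phase"), names(df))
  agg <- function(by_cols) {
    by <- df[, by_cols, drop = FALSE]
    out <- stats::aggregate(df[vals], by = by, FUN = mean)
    out[do.call(order, out[by_cols]), , drop = FALSE]
  }
  by_cultivar <- agg(c("cultivar", "class", keys))
  by_class <- agg(c("class", keys))
  early <- by_class[by_class$class == "early", , drop = FALSE]
  late <- by_class[by_class$class == "mid-late", , drop = FALSE]
  if (nrow(early) && nrow(late)) {
    if (length(keys)) {
      m <- merge(late, early, by = keys, suffixes = c(".late", ".early"))
      diff <- m[, keys, drop = FALSE]
      for (v in vals) diff[[v]] <- m[[paste0(v, ".late")]] -
          m[[paste0(v, ".early")]]
    } else {
      diff <- as.data.frame(as.list(
        unlist(late[vals]) - unlist(early[vals])))
      names(diff) <- vals
    }
  } else diff <- NULL
  rownames(by_cultivar) <- rownames(by_class) <- NULL
  if (!is.null(diff)) rownames(diff) <- NULL
  list(by_cultivar = by_cultivar, by_class = by_class, class_diff = diff)
}
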