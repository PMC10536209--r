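#' Chill and anti-chill days model parameters
#'
#' The sprouting model has two parameters: the threshold temperature `tc`
#' (deg C) separating chilling from forcing conditions, and the chilling
#' requirement `cr`, a negative total of chill units that must accumulate
#' before endo-dormancy is released.
#'
#' @param tc Threshold temperature in deg C; must be positive.
#' @param cr Chilling requirement in chill units; must be negative.
#' @return An object of class `cac_params`.
#' @examples
#' cac_params(tc = 9.5, cr = -115)
#' @export
cac_params <- function(tc, cr) {
  stopifnot(is.numeric(tc), length(tc) == 1L, is.finite(tc),
            is.numeric(cr), length(cr) == 1L, is.finite(cr))
  if (tc <= 0) stop("`tc` must be positive (deg C)", call. = FALSE)
  if (cr >= 0) stop("`cr` must be negative (chill units)", call. = FALSE)
  structure(list(tc = as.numeric(tc), cr = as.numeric(cr)),
            class = "cac_params")
}

#' Growing degree days parameters
#'
#' Forcing parameters for one phenological phase: base temperature `tb`,
#' upper threshold `tx_base` (both deg C; daily extremes are clamped into
#' `[tb, tx_base]` before averaging) and the heating requirement `hr` in
#' GDD units at which the phase occurs.
#'
#' @param tb Base temperature, deg C.
#' @param tx_base Upper temperature threshold, deg C; must exceed `tb`.
#' @param hr Heating requirement in GDD units; must be positive.
#' @return An object of class `gdd_params`.
#' @examples
#' gdd_params(tb = 5.9, tx_base = 31.5, hr = 437)
#' @export
gdd_params <- function(tb, tx_base, hr) {
  stopifnot(is.numeric(tb), length(tb) == 1L, is.finite(tb),
            is.numeric(tx_base), length(tx_base) == 1L, is.finite(tx_base),
            is.numeric(hr), length(hr) == 1L, is.finite(hr))
  if (tb >= tx_base) stop("`tb` must be below `tx_base`", call. = FALSE)
  if (hr <= 0) stop("`hr` must be positive (GDD units)", call. = FALSE)
  structure(list(tb = as.numeric(tb), tx_base = as.numeric(tx_base),
                 hr = as.numeric(hr)),
            class = "gdd_params")
}

#' Full parameter set for one cultivar
#'
#' Bundles the chill model parameters with the two forcing parameter sets.
#' Blooming and pit hardening share the same `tb` and `tx_base`; only the
#' heating requirement differs, and the pit-hardening requirement must be
#' the larger one since both accumulate from the sprouting date.
#'
#' @param cultivar Cultivar name.
#' @param class Budbreak class, `"early"` or `"mid-late"`.
#' @param cac A [cac_params()] object.
#' @param gdd_bloom,gdd_pit [gdd_params()] objects for blooming and pit
#'   hardening.
#' @return An object of class `cultivar_params`.
#' @export
cultivar_params <- function(cultivar, class = c("early", "mid-late"),
                            cac, gdd_bloom, gdd_pit) {
  class <- match.arg(class)
  stopifnot(inherits(cac, "cac_params"),
            inherits(gdd_bloom, "gdd_params"),
            inherits(gdd_pit, "gdd_params"))
  if (gdd_pit$tb != gdd_bloom$tb || gdd_pit$tx_base != gdd_bloom$tx_base)
    stop("blooming and pit hardening must share `tb` and `tx_base`",
         call. = FALSE)
  if (gdd_pit$hr <= gdd_bloom$hr)
    stop("pit-hardening `hr` must exceed the blooming `hr`", call. = FALSE)
  structure(list(cultivar = as.character(cultivar), class = class,
                 cac = cac, gdd_bloom = gdd_bloom, gdd_pit = gdd_pit),
            class = "cultivar_params")
}

#' @export
print.cac_params <- function(x, ...) {
  cat(sprintf("Chill/anti-chill parameters: Tc = %g degC, Cr = %g chill units\n",
              x$tc, x$cr))
  invisible(x)
}

#' @export
print.gdd_params <- function(x, ...) {
  cat(sprintf("GDD parameters: Tb = %g degC, Tx.base = %g degC, Hr = %g GDD\n",
              x$tb, x$tx_base, x$hr))
  invisible(x)
}

#' @export
print.cultivar_params <- function(x, ...) {
  cat(sprintf("Cultivar '%s' (%s budbreak)\n", x$cultivar, x$class))
  cat("  sprouting:     "); print(x$cac)
  cat("  blooming:      "); print(x$gdd_bloom)
  cat("  pit hardening: "); print(x$gdd_pit)
  invisible(x)
}

#' Read or write a cultivar parameter file
#'
#' Cultivar parameters travel as a flat key-value YAML file with keys
#' `cultivar`, `class`, `tc`, `cr`, `tb`, `tx_base`, `hr_bloom`, `hr_pit`.
#'
#' @param path File path.
#' @return `read_cultivar_params()` returns a [cultivar_params()] object;
#'   `write_cultivar_params()` invisibly returns `path`.
#' @export
read_cultivar_params <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path, call. = FALSE)
  kv <- yaml::read_yaml(path)
  need <- c("cultivar", "class", "tc", "cr", "tb", "tx_base",
            "hr_bloom", "hr_pit")
  missing <- setdiff(need, names(kv))
  if (length(missing))
    stop("parameter file misses key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cultivar_params(kv$cultivar, kv$class,
                  cac = cac_params(kv$tc, kv$cr),
                  gdd_bloom = gdd_params(kv$tb, kv$tx_base, kv$hr_bloom),
                  gdd_pit = gdd_params(kv$tb, kv$tx_base, kv$hr_pit))
}

#' @rdname read_cultivar_params
#' @param cv A [cultivar_params()] object.
#' @export
write_cultivar_params <- function(cv, path) {
  stopifnot(inherits(cv, "cultivar_params"))
  yaml::write_yaml(list(cultivar = cv$cultivar, class = cv$class,
                        tc = cv$cac$tc, cr = cv$cac$cr,
                        tb = cv$gdd_bloom$tb, tx_base = cv$gdd_bloom$tx_base,
                        hr_bloom = cv$gdd_bloom$hr, hr_pit = cv$gdd_pit$hr),
                   path)
  invisible(path)
}

#' Box bounds for bounded optimization
#'
#' @param lower,upper Named numeric vectors of identical length and names;
#'   every lower bound must be strictly below its upper bound.
#' @return An object of class `parameter_bounds`.
#' @export
parameter_bounds <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == length(upper), length(lower) >= 1L,
            all(is.finite(lower)), all(is.finite(upper)))
  if (!is.null(names(lower)) && !is.null(names(upper)) &&
      !identical(names(lower), names(upper)))
    stop("bound names disagree", call. = FALSE)
  if (any(lower >= upper))
    stop("every lower bound must be strictly below its upper bound",
         call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "parameter_bounds")
}

#' Default calibration search bounds
#'
#' `cac_bounds()` returns the search box for the sprouting model
#' (Tc in 7-14 deg C, Cr in -200..-80 chill units); `gdd_bounds()` the box
#' for the forcing model (Tb 4-10 deg C, Tx.base 25-35 deg C,
#' Hr 300-1400 GDD).
#'
#' @return A [parameter_bounds()] object.
#' @export
cac_bounds <- function() {
  parameter_bounds(c(tc = 7, cr = -200), c(tc = 14, cr = -80))
}

#' @rdname cac_bounds
#' @export
gdd_bounds <- function() {
  parameter_bounds(c(tb = 4, tx_base = 25, hr = 300),
                   c(tb = 10, tx_base = 35, hr = 1400))
}
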