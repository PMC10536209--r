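# Packaged reference tables: published mean observed phenological dates and
# genetic-algorithm-calibrated parameter sets for four Italian olive
# cultivars (Carolea and Picholine, early budbreak; Frantoio and Moraiolo,
# mid-late budbreak).

#' Reference mean phenological dates
#'
#' Mean observed Julian days of sprouting, blooming and pit hardening for
#' the four reference cultivars, as a tidy table with one row per cultivar
#' and phase.
#'
#' @return Data frame with columns `cultivar`, `class`, `phase`,
#'   `mean_jday`.
#' @examples
#' olive_phase_means()
#' @export
olive_phase_means <- function() {
  utils::read.csv(system.file("extdata", "olive_phase_means.csv",
                              package = "cacgdd"),
                  stringsAsFactors = FALSE)
}

#' Reference calibrated parameter table
#'
#' Calibrated model parameters for the four reference cultivars: chill
#' model (`tc`, `cr`) for sprouting and forcing model (`tb`, `tx_base`,
#' `hr_bloom`, `hr_pit`) for blooming and pit hardening. Blooming and pit
#' hardening share `tb`/`tx_base`; both heating requirements count from the
#' sprouting date.
#'
#' @return Data frame with one row per cultivar.
#' @examples
#' olive_cultivar_params()
#' @export
olive_cultivar_params <- function() {
  utils::read.csv(system.file("extdata", "olive_cultivar_params.csv",
                              package = "cacgdd"),
                  stringsAsFactors = FALSE)
}

#' Reference parameters for one cultivar as a model object
#'
#' @param cultivar One of `"Carolea"`, `"Picholine"`, `"Frantoio"`,
#'   `"Moraiolo"`.
#' @return A [cultivar_params()] object.
#' @examples
#' reference_cultivar("Carolea")
#' @export
reference_cultivar <- function(cultivar) {
  tab <- olive_cultivar_params()
  row <- tab[tab$cultivar == cultivar, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown cultivar '", cultivar, "'; available: ",
         paste(tab$cultivar, collapse = ", "), call. = FALSE)
  cultivar_params(row$cultivar, row$class,
                  cac = cac_params(row$tc, row$cr),
                  gdd_bloom = gdd_params(row$tb, row$tx_base, row$hr_bloom),
                  gdd_pit = gdd_params(row$tb, row$tx_base, row$hr_pit))
}

#' All packaged fixture tables
#'
#' @return List with elements `phase_means` and `cultivar_params`.
#' @export
packaged_fixtures <- function() {
  list(phase_means = olive_phase_means(),
       cultivar_params = olive_cultivar_params())
}
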