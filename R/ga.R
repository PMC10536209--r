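# Bounded real-valued genetic algorithm used for parameter calibration.
# Any bounded, seed-deterministic global optimizer could stand behind this
# interface; the default scheme is tournament selection, blend crossover,
# Gaussian mutation with bound clipping, and elitism.

#' Genetic algorithm settings
#'
#' @param population_size Individuals per generation (>= 4).
#' @param max_generations Generation cap. The published calibration setting
#'   is 1000; smaller values trade accuracy for speed.
#' @param crossover_prob Probability that a pair of parents is recombined.
#' @param mutation_prob Per-gene probability of a Gaussian perturbation.
#' @param elitism Number of best individuals copied unchanged.
#' @param early_stop_patience Stop after this many generations without
#'   improvement of the best objective value.
#' @param seed Mandatory integer seed; the optimizer is fully deterministic
#'   given the seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, max_generations = 1000L,
                      crossover_prob = 0.8, mutation_prob = 0.1,
                      elitism = 2L, early_stop_patience = 100L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(population_size >= 4L, max_generations >= 1L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            elitism >= 0L, elitism < population_size,
            early_stop_patience >= 1L,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism = as.integer(elitism),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# run `expr` under a local RNG stream so the caller's RNG state survives
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Minimize an objective with a bounded genetic algorithm
#'
#' Minimizes `objective` (equivalently, maximizes its negative as fitness)
#' over the box given by `bounds`. The population is initialized uniformly
#' within the bounds; children are produced by tournament selection, blend
#' crossover and per-gene Gaussian mutation (sd = 10% of the bound width),
#' clipped back into the box, with the best `elitism` individuals carried
#' over unchanged, so the best value never worsens across generations.
#' The run is bit-reproducible for a given `config$seed`.
#'
#' @param objective Function taking a numeric parameter vector and
#'   returning a finite scalar to minimize (here: an RMSE in days).
#' @param bounds A [parameter_bounds()] object.
#' @param config A [ga_config()] object.
#' @return An object of class `calibration_result`: list with `par` (named
#'   best parameters, inside the bounds), `value` (best objective),
#'   `fitness_trace` (per-generation best), `generations`, `seed` and
#'   `bounds`.
#' @export
ga_optimize <- function(objective, bounds, config) {
  stopifnot(is.function(objective), inherits(bounds, "parameter_bounds"),
            inherits(config, "ga_config"))
  lower <- bounds$lower; upper <- bounds$upper
  d <- length(lower)
  width <- upper - lower
  pop_n <- config$population_size

  eval_one <- function(par) {
    v <- objective(par)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("objective is not finite at (",
           paste(sprintf("%.6g", par), collapse = ", "), ")", call. = FALSE)
    v
  }

  .with_seed(config$seed, {
    pop <- matrix(stats::runif(pop_n * d, rep(lower, each = pop_n),
                               rep(upper, each = pop_n)),
                  nrow = pop_n, ncol = d)
    val <- apply(pop, 1L, eval_one)
    trace <- numeric(0)
    best_val <- Inf; best_par <- pop[1L, ]
    stagnant <- 0L
    gens <- 0L
    for (gen in seq_len(config$max_generations)) {
      gens <- gen
      ord <- order(val)
      gen_best <- val[ord[1L]]
      if (gen_best < best_val - 1e-12) {
        best_val <- gen_best; best_par <- pop[ord[1L], ]
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      trace <- c(trace, min(best_val, gen_best))
      if (stagnant >= config$early_stop_patience) break
      if (gen == config$max_generations) break

      elite_idx <- ord[seq_len(config$elitism)]
      n_child <- pop_n - config$elitism
      # binary tournament on the minimized objective
      pick <- function(k) {
        a <- sample.int(pop_n, k, replace = TRUE)
        b <- sample.int(pop_n, k, replace = TRUE)
        ifelse(val[a] <= val[b], a, b)
      }
      p1 <- pop[pick(n_child), , drop = FALSE]
      p2 <- pop[pick(n_child), , drop = FALSE]
      u <- matrix(stats::runif(n_child * d), n_child, d)
      child <- u * p1 + (1 - u) * p2
      no_cx <- stats::runif(n_child) > config$crossover_prob
      child[no_cx, ] <- p1[no_cx, , drop = FALSE]
      mut <- matrix(stats::runif(n_child * d) < config$mutation_prob,
                    n_child, d)
      if (any(mut)) {
        noise <- matrix(stats::rnorm(n_child * d,
                                     sd = rep(0.1 * width, each = n_child)),
                        n_child, d)
        child[mut] <- child[mut] + noise[mut]
      }
      child <- pmin(pmax(child, rep(lower, each = n_child)),
                    rep(upper, each = n_child))
      child_val <- apply(child, 1L, eval_one)
      pop <- rbind(pop[elite_idx, , drop = FALSE], child)
      val <- c(val[elite_idx], child_val)
    }
    names(best_par) <- names(lower)
    structure(list(par = best_par, value = best_val,
                   fitness_trace = trace, generations = gens,
                   seed = config$seed, bounds = bounds),
              class = "calibration_result")
  })
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration result (seed %d, %d generations)\n",
              x$seed, x$generations))
  cat("  best parameters:",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "), "\n")
  cat(sprintf("  best RMSE: %.4f days\n", x$value))
  invisible(x)
}

#' Write a calibration report
#'
#' Structured YAML report with the best parameters, their RMSE, the seed,
#' the bounds searched and the fitness trace.
#'
#' @param result A `calibration_result` from [ga_optimize()],
#'   [calibrate_cac()] or [calibrate_gdd()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_calibration_report <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  yaml::write_yaml(list(best_params = as.list(result$par),
                        best_rmse_days = result$value,
                        generations = result$generations,
                        seed = result$seed,
                        bounds = list(lower = as.list(result$bounds$lower),
                                      upper = as.list(result$bounds$upper)),
                        fitness_trace = result$fitness_trace),
                   path)
  invisible(path)
}
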