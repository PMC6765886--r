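#' Monte Carlo simulation settings
#'
#' @param n_iterations Number of iterations (>= 1). The published analysis used
#'   1000; larger values are recommended for stable interval bounds.
#' @param seed Integer seed; every run is reproducible from it. \code{NULL}
#'   continues the current RNG stream.
#' @param interval_mass Central probability mass of the prediction interval
#'   (default 0.90, i.e. the empirical 5th and 95th percentiles).
#' @return An object of class \code{sim_settings}.
#' @export
sim_settings <- function(n_iterations = 1000, seed = NULL, interval_mass = 0.90) {
  stopifnot(is.numeric(n_iterations), length(n_iterations) == 1L, n_iterations >= 1,
            is.numeric(interval_mass), length(interval_mass) == 1L,
            interval_mass > 0, interval_mass < 1)
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    seed <- as.integer(seed)
  }
  structure(list(n_iterations = as.integer(n_iterations), seed = seed,
                 interval_mass = interval_mass),
            class = "sim_settings")
}

#' Empirical quantile by linear interpolation
#'
#' Linear interpolation on the order statistics (the classic sample quantile
#' with \code{q = 0} giving the minimum and \code{q = 1} the maximum).
#'
#' @param samples Non-empty numeric vector.
#' @param q Probability level(s) in \[0, 1\].
#' @return The empirical quantile(s).
#' @export
empirical_quantile <- function(samples, q) {
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  unname(stats::quantile(samples, probs = q, type = 7, names = FALSE))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Run a Monte Carlo simulation of a scenario
#'
#' Draws every uncertain (triangular) input of the scenario independently
#' across inputs and iterations by inverse-CDF sampling, evaluates the model
#' chain once per iteration, and summarizes the primary output with its
#' arithmetic mean and the central \code{interval_mass} empirical prediction
#' interval. Per-iteration input draws are retained so sensitivity analyses
#' can condition on input bins without re-running the simulation.
#'
#' @param scenario A \code{\link{mortality_scenario}} or
#'   \code{\link{initiation_scenario}} (validated again before running).
#' @param settings A \code{\link{sim_settings}} object.
#' @return An object of class \code{simulation_result}: a list with
#'   \code{outputs} (named list of per-iteration output channels, primary
#'   first), \code{draws} (named list of per-input draws), \code{mean},
#'   \code{interval_low}, \code{interval_high}, \code{primary_output},
#'   \code{settings} and \code{scenario}.
#' @examples
#' res <- run_simulation(mortality_scenario(), sim_settings(1000, seed = 1))
#' res$mean
#' @export
run_simulation <- function(scenario, settings = sim_settings()) {
  validate_scenario(scenario)
  stopifnot(inherits(settings, "sim_settings"))
  n <- settings$n_iterations
  dists <- scenario_distributions(scenario)
  draws <- with_seed(settings$seed,
                     lapply(dists, function(d) tri_sample(d, n)))
  outputs <- eval_model(scenario, draws)
  primary <- outputs[[1L]]
  alpha <- (1 - settings$interval_mass) / 2
  bounds <- empirical_quantile(primary, c(alpha, 1 - alpha))
  stopifnot(bounds[1] <= bounds[2])
  structure(list(outputs = outputs,
                 draws = draws,
                 mean = mean(primary),
                 interval_low = bounds[1],
                 interval_high = bounds[2],
                 primary_output = names(outputs)[1L],
                 settings = settings,
                 scenario = scenario),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %s, %d iterations%s>\n",
              x$primary_output, x$settings$n_iterations,
              if (is.null(x$settings$seed)) "" else
                sprintf(", seed %d", x$settings$seed)))
  cat(sprintf("  mean %.4g, %g%% prediction interval [%.4g, %.4g]\n",
              x$mean, 100 * x$settings$interval_mass,
              x$interval_low, x$interval_high))
  invisible(x)
}

#' Closed-form expected value of a scenario's primary output
#'
#' Uses the independence of the sampled inputs: for the mortality chain,
#' deaths x E\[consumption reduction\] x E\[cessation fraction\]; for the
#' initiation chain, base x (E\[D\] + (1 - E\[D\]) E\[C\]) where D is the
#' initiation reduction and C the continuing-use reduction
#' (E\[D + (1 - D)C\] = E\[D\] + (1 - E\[D\])E\[C\] because D and C are
#' independent). The analytic counterpart of the Monte Carlo mean.
#'
#' @param scenario A scenario object.
#' @return Expected value of the primary output.
#' @export
analytic_expectation <- function(scenario) {
  UseMethod("analytic_expectation")
}

#' @export
analytic_expectation.mortality_scenario <- function(scenario) {
  scenario$attributable_deaths *
    tri_mean(scenario$consumption_reduction) *
    tri_mean(scenario$cessation_fraction)
}

#' @export
analytic_expectation.initiation_scenario <- function(scenario) {
  base <- flavored_initiate_base(scenario$cohort_size,
                                 scenario$current_use_prevalence,
                                 scenario$flavored_initiation_fraction)
  ed <- tri_mean(scenario$initiation_reduction)
  ec <- tri_mean(scenario$continuing_reduction)
  base * (ed + (1 - ed) * ec)
}
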