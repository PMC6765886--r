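#' One-way sensitivity by conditional output means over input bins
#'
#' Ranks the retained iterations of a simulation by one sampled input, splits
#' them into \code{n_bins} equal-count bins, and reports the mean of the
#' primary output within the lowest and highest bins. This quantifies how much
#' of the output's spread that input drives while the other inputs vary over
#' their distributions (their effect averages out within each bin). With
#' decile bins this reconstructs the published one-way ranges, which are far
#' narrower than naive min/max substitution because the conditioning input is
#' averaged over its outer deciles, not pinned at its extremes.
#'
#' @param result A \code{\link{run_simulation}} result.
#' @param input_name Name of a retained input draw.
#' @param n_bins Number of equal-count bins (>= 2); the simulation must have at
#'   least \code{10 * n_bins} iterations.
#' @return A one-row data frame with columns \code{input_name}, \code{method}
#'   ("conditional_mean"), \code{low}, \code{high} and \code{n_bins}.
#' @export
conditional_mean_range <- function(result, input_name, n_bins = 10) {
  stopifnot(inherits(result, "simulation_result"),
            is.numeric(n_bins), length(n_bins) == 1L, n_bins >= 2)
  if (!input_name %in% names(result$draws)) {
    stop(sprintf("unknown input '%s'; retained inputs: %s", input_name,
                 paste(names(result$draws), collapse = ", ")), call. = FALSE)
  }
  n <- result$settings$n_iterations
  if (n < 10 * n_bins) {
    stop("need at least 10 iterations per bin", call. = FALSE)
  }
  x <- result$draws[[input_name]]
  y <- result$outputs[[1L]]
  bin <- ceiling(rank(x, ties.method = "first") / (n / n_bins))
  data.frame(input_name = input_name,
             method = "conditional_mean",
             low = mean(y[bin == 1]),
             high = mean(y[bin == n_bins]),
             n_bins = as.integer(n_bins),
             stringsAsFactors = FALSE)
}

#' One-at-a-time deterministic sensitivity
#'
#' Evaluates the model chain at one input's minimum and maximum with every
#' other uncertain input held at its mode. The deterministic complement to
#' \code{\link{conditional_mean_range}}: it shows the full input range's
#' leverage rather than an outer-bin average.
#'
#' @param scenario A scenario object.
#' @param input_name Name of a triangular input of the scenario.
#' @return A one-row data frame with columns \code{input_name}, \code{method}
#'   ("one_at_a_time"), \code{low}, \code{high} and \code{n_bins} (NA).
#' @export
one_at_a_time <- function(scenario, input_name) {
  dists <- scenario_distributions(scenario)
  if (!input_name %in% names(dists)) {
    stop(sprintf("unknown input '%s'; triangular inputs: %s", input_name,
                 paste(names(dists), collapse = ", ")), call. = FALSE)
  }
  at <- function(value) {
    draws <- lapply(dists, function(d) d$mode)
    draws[[input_name]] <- value
    eval_model(scenario, draws)[[1L]]
  }
  data.frame(input_name = input_name,
             method = "one_at_a_time",
             low = at(dists[[input_name]]$minimum),
             high = at(dists[[input_name]]$maximum),
             n_bins = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Tornado table: both sensitivity methods for every uncertain input
#'
#' @param result A \code{\link{run_simulation}} result.
#' @param n_bins Bins for the conditional-mean method (default deciles).
#' @return A data frame with one conditional-mean row and one one-at-a-time
#'   row per uncertain input, so the reconstruction's assumptions are visible
#'   side by side.
#' @export
tornado <- function(result, n_bins = 10) {
  stopifnot(inherits(result, "simulation_result"))
  inputs <- names(result$draws)
  rows <- c(lapply(inputs, function(nm) conditional_mean_range(result, nm, n_bins)),
            lapply(inputs, function(nm) one_at_a_time(result$scenario, nm)))
  do.call(rbind, rows)
}
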