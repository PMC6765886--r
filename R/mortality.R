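#' Premature deaths avoided per year through increased cessation
#'
#' The cessation-mortality chain: attributable deaths among exclusive regular
#' cigar smokers, times the proportional reduction in cigar consumption the
#' policy produces, times the fraction of that reduction that is complete
#' cessation. Smokers who merely cut back receive no mortality benefit, and
#' prevalence is assumed constant absent the policy, so the result reads as
#' deaths avoided per year at steady state. No rounding is applied.
#'
#' @param attributable_deaths Deaths/year among exclusive regular cigar
#'   smokers (non-negative). Vectorized.
#' @param consumption_reduction Proportion in \[0, 1\]. Vectorized.
#' @param cessation_fraction Proportion in \[0, 1\]. Vectorized.
#' @return Deaths avoided per year (real, unrounded).
#' @examples
#' deaths_avoided(5200, 0.30, 0.50) # 780
#' @export
deaths_avoided <- function(attributable_deaths, consumption_reduction,
                           cessation_fraction) {
  if (any(attributable_deaths < 0) || any(consumption_reduction < 0) ||
      any(cessation_fraction < 0)) {
    stop("all inputs must be non-negative", call. = FALSE)
  }
  if (any(consumption_reduction > 1) || any(cessation_fraction > 1)) {
    stop("proportions must not exceed 1", call. = FALSE)
  }
  attributable_deaths * consumption_reduction * cessation_fraction
}

#' Flavored share of the national cigar market
#'
#' Product of the machine-made share of cigars sold and the flavored share of
#' machine-made retail sales, assuming hand-made cigars are generally not
#' flavored. This product is the rationale behind the upper bound of the
#' consumption-reduction distribution; the configured upper bound remains the
#' tabulated value (45%), not this exact product (0.92 x 0.521 = 0.47932).
#'
#' @param machine_made_share,flavored_retail_share Proportions in \[0, 1\].
#' @return The product, a proportion.
#' @export
flavored_market_share_bound <- function(machine_made_share, flavored_retail_share) {
  stopifnot(machine_made_share >= 0, machine_made_share <= 1,
            flavored_retail_share >= 0, flavored_retail_share <= 1)
  machine_made_share * flavored_retail_share
}

#' Deterministic point estimate of a scenario
#'
#' Evaluates the model chain with every uncertain input at its triangular mode
#' (the main-analysis values), carrying full precision throughout.
#'
#' @param scenario A scenario object.
#' @return For a mortality scenario, a list with \code{deaths_avoided}. For an
#'   initiation scenario, a list with the full chain:
#'   \code{current_users}, \code{flavored_base}, \code{initiates_prevented},
#'   \code{continuing_prevented}, \code{total_prevented},
#'   \code{prevalence_reduction}.
#' @examples
#' point_estimate(mortality_scenario())$deaths_avoided # 780
#' @export
point_estimate <- function(scenario) {
  UseMethod("point_estimate")
}

#' @export
point_estimate.mortality_scenario <- function(scenario) {
  list(deaths_avoided = deaths_avoided(scenario$attributable_deaths,
                                       scenario$consumption_reduction$mode,
                                       scenario$cessation_fraction$mode))
}

# Evaluate the model chain for given values of the uncertain inputs.
# `draws` is a named list of equal-length numeric vectors, one per
# triangular input; returns a named list of output channels, the first of
# which is the primary output.
eval_model <- function(scenario, draws) {
  UseMethod("eval_model")
}

#' @export
eval_model.mortality_scenario <- function(scenario, draws) {
  list(deaths_avoided = deaths_avoided(scenario$attributable_deaths,
                                       draws$consumption_reduction,
                                       draws$cessation_fraction))
}
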