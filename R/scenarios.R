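#' Mortality (cessation) scenario
#'
#' Inputs for the cessation-mortality chain: annual premature deaths among
#' exclusive regular cigar smokers, the proportional reduction in total cigar
#' consumption a flavor prohibition would produce, and the fraction of that
#' reduction attributable to complete cessation (the only route given a
#' mortality benefit). Defaults encode the published national analysis:
#' 5200 attributable deaths/year, consumption reduction Tri(15%, 30%, 45%)
#' and cessation fraction Tri(25%, 50%, 75%). The machine-made and flavored
#' retail market shares document the rationale for the 45% upper consumption
#' bound (see \code{\link{flavored_market_share_bound}}); the configured upper
#' bound itself is the tabulated 45%, not the exact product.
#'
#' @param attributable_deaths Premature deaths per year among exclusive regular
#'   cigar smokers (> 0). Dual users are excluded by construction.
#' @param consumption_reduction \code{\link{triangular}} proportion.
#' @param cessation_fraction \code{\link{triangular}} proportion.
#' @param machine_made_share,flavored_retail_share Proportions in \[0, 1\].
#' @return An object of class \code{c("mortality_scenario", "scenario")}.
#' @export
mortality_scenario <- function(attributable_deaths = 5200,
                               consumption_reduction = triangular(0.15, 0.30, 0.45),
                               cessation_fraction = triangular(0.25, 0.50, 0.75),
                               machine_made_share = 0.92,
                               flavored_retail_share = 0.521) {
  s <- structure(
    list(attributable_deaths = attributable_deaths,
         consumption_reduction = consumption_reduction,
         cessation_fraction = cessation_fraction,
         machine_made_share = machine_made_share,
         flavored_retail_share = flavored_retail_share),
    class = c("mortality_scenario", "scenario"))
  validate_scenario(s)
  s
}

#' Initiation and continuing-use scenario
#'
#' Inputs for the cohort chain: 18-year-old cohort size, current cigar-use
#' prevalence at that age, the fraction of current users who initiated with a
#' flavored product, the uncertain reduction in initiation under a flavor
#' prohibition, and the uncertain reduction in continuing use among
#' non-deterred flavored initiates. The continuing-use reduction's mode is
#' derived from the adjusted prevalence ratio of current regular use for
#' flavored vs non-flavored initiates as 1 - 1/ratio; its min and max come
#' from the ratio's 95% confidence bounds (1.29, 1.87). Defaults encode the
#' published analysis: 4.2 million 18 year olds, 7.2% prevalence
#' (every-day/some-day use; 13.1% past-30-day is a supported alternative,
#' not the default), 65.4% flavored initiation, initiation reduction
#' Tri(0, 32.5%, 65%), prevalence ratio 1.56 and continuing reduction
#' Tri(22.5%, 35.9%, 46.5%).
#'
#' @param cohort_size Persons in the cohort (> 0).
#' @param current_use_prevalence Proportion of the cohort currently using cigars.
#' @param flavored_initiation_fraction Proportion of current users who initiated
#'   with a flavored cigar.
#' @param initiation_reduction \code{\link{triangular}} proportion.
#' @param continuing_prevalence_ratio Adjusted prevalence ratio (> 0).
#' @param continuing_reduction \code{\link{triangular}} proportion; its mode
#'   must equal \code{1 - 1/continuing_prevalence_ratio} to three decimals
#'   (checked at construction, never silently re-derived).
#' @return An object of class \code{c("initiation_scenario", "scenario")}.
#' @export
initiation_scenario <- function(cohort_size = 4.2e6,
                                current_use_prevalence = 0.072,
                                flavored_initiation_fraction = 0.654,
                                initiation_reduction = triangular(0, 0.325, 0.65),
                                continuing_prevalence_ratio = 1.56,
                                continuing_reduction = triangular(0.225, 0.359, 0.465)) {
  s <- structure(
    list(cohort_size = cohort_size,
         current_use_prevalence = current_use_prevalence,
         flavored_initiation_fraction = flavored_initiation_fraction,
         initiation_reduction = initiation_reduction,
         continuing_prevalence_ratio = continuing_prevalence_ratio,
         continuing_reduction = continuing_reduction),
    class = c("initiation_scenario", "scenario"))
  validate_scenario(s)
  s
}

#' Validate a scenario
#'
#' Checks every field invariant and reports all violations at once, naming
#' the offending fields.
#'
#' @param scenario A scenario object.
#' @return The scenario, invisibly, if valid; otherwise an error listing every
#'   offending field.
#' @export
validate_scenario <- function(scenario) {
  UseMethod("validate_scenario")
}

check_proportion <- function(value, name, problems) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    problems <- c(problems, sprintf("%s: must be a proportion in [0, 1]", name))
  }
  problems
}

check_tri_proportion <- function(dist, name, problems) {
  if (!is_triangular(dist)) {
    problems <- c(problems, sprintf("%s: must be a triangular distribution", name))
  } else if (dist$minimum < 0 || dist$maximum > 1) {
    problems <- c(problems, sprintf("%s: support must lie within [0, 1]", name))
  }
  problems
}

fail_validation <- function(problems) {
  if (length(problems)) {
    stop("invalid scenario:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  }
}

#' @export
validate_scenario.mortality_scenario <- function(scenario) {
  p <- character()
  if (!is.numeric(scenario$attributable_deaths) ||
      length(scenario$attributable_deaths) != 1L ||
      is.na(scenario$attributable_deaths) || scenario$attributable_deaths <= 0) {
    p <- c(p, "attributable_deaths: must be a positive count")
  }
  p <- check_tri_proportion(scenario$consumption_reduction, "consumption_reduction", p)
  p <- check_tri_proportion(scenario$cessation_fraction, "cessation_fraction", p)
  p <- check_proportion(scenario$machine_made_share, "machine_made_share", p)
  p <- check_proportion(scenario$flavored_retail_share, "flavored_retail_share", p)
  fail_validation(p)
  invisible(scenario)
}

#' @export
validate_scenario.initiation_scenario <- function(scenario) {
  p <- character()
  if (!is.numeric(scenario$cohort_size) || length(scenario$cohort_size) != 1L ||
      is.na(scenario$cohort_size) || scenario$cohort_size <= 0) {
    p <- c(p, "cohort_size: must be a positive count")
  }
  p <- check_proportion(scenario$current_use_prevalence, "current_use_prevalence", p)
  p <- check_proportion(scenario$flavored_initiation_fraction,
                        "flavored_initiation_fraction", p)
  p <- check_tri_proportion(scenario$initiation_reduction, "initiation_reduction", p)
  p <- check_tri_proportion(scenario$continuing_reduction, "continuing_reduction", p)
  if (!is.numeric(scenario$continuing_prevalence_ratio) ||
      length(scenario$continuing_prevalence_ratio) != 1L ||
      is.na(scenario$continuing_prevalence_ratio) ||
      scenario$continuing_prevalence_ratio <= 0) {
    p <- c(p, "continuing_prevalence_ratio: must be a positive ratio")
  } else if (is_triangular(scenario$continuing_reduction)) {
    derived <- continuing_reduction_from_ratio(scenario$continuing_prevalence_ratio)
    if (abs(round(derived, 3) - round(scenario$continuing_reduction$mode, 3)) > 5e-4) {
      p <- c(p, sprintf(
        "continuing_reduction: mode (%g) must equal 1 - 1/prevalence ratio (%.3f) to three decimals",
        scenario$continuing_reduction$mode, derived))
    }
  }
  fail_validation(p)
  invisible(scenario)
}

# Named list of the scenario's uncertain (triangular) inputs.
scenario_distributions <- function(scenario) {
  UseMethod("scenario_distributions")
}

#' @export
scenario_distributions.mortality_scenario <- function(scenario) {
  list(consumption_reduction = scenario$consumption_reduction,
       cessation_fraction = scenario$cessation_fraction)
}

#' @export
scenario_distributions.initiation_scenario <- function(scenario) {
  list(initiation_reduction = scenario$initiation_reduction,
       continuing_reduction = scenario$continuing_reduction)
}

#' @export
print.scenario <- function(x, ...) {
  kind <- if (inherits(x, "mortality_scenario")) "mortality (cessation)" else
    "initiation / continuing use"
  cat(sprintf("<%s scenario>\n", kind))
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is_triangular(v)) {
      cat(sprintf("  %s: Tri(%g, %g, %g)\n", nm, v$minimum, v$mode, v$maximum))
    } else {
      cat(sprintf("  %s: %g\n", nm, v))
    }
  }
  invisible(x)
}
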