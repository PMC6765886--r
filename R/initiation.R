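#' Continuing-use reduction implied by a prevalence ratio
#'
#' If flavored initiates are \code{ratio} times as likely to be current
#' regular users as non-flavored initiates, removing flavors is modelled as
#' reducing continuing use among would-have-been flavored initiates by
#' \code{1 - 1/ratio}.
#'
#' @param prevalence_ratio Adjusted prevalence ratio (> 0). Vectorized.
#' @return Proportion \code{1 - 1/prevalence_ratio}.
#' @examples
#' continuing_reduction_from_ratio(1.56) # 0.359 to three decimals
#' @export
continuing_reduction_from_ratio <- function(prevalence_ratio) {
  if (any(prevalence_ratio <= 0)) {
    stop("prevalence_ratio must be positive", call. = FALSE)
  }
  1 - 1 / prevalence_ratio
}

#' Current cigar users who initiated with a flavored product
#'
#' The base of the deterrence chain: cohort size times current-use prevalence
#' times the fraction of current users whose first cigar was flavored.
#' Unrounded (4,200,000 x 0.072 x 0.654 = 197,769.6; reported as 198,000 only
#' at the reporting layer).
#'
#' @param cohort_size Persons (non-negative). Vectorized.
#' @param prevalence,flavored_fraction Proportions in \[0, 1\]. Vectorized.
#' @return Persons (real, unrounded).
#' @export
flavored_initiate_base <- function(cohort_size, prevalence, flavored_fraction) {
  stopifnot(all(cohort_size >= 0), all(prevalence >= 0), all(prevalence <= 1),
            all(flavored_fraction >= 0), all(flavored_fraction <= 1))
  cohort_size * prevalence * flavored_fraction
}

#' Cigar users prevented by deterred initiation and reduced continuation
#'
#' Splits the flavored-initiate base into the two deterrence routes: initiates
#' prevented outright (\code{base * initiation_reduction}) and continuing users
#' prevented among those who still initiate
#' (\code{base * (1 - initiation_reduction) * continuing_reduction}). All
#' values unrounded.
#'
#' @param base Flavored-initiate base, persons. Vectorized.
#' @param initiation_reduction,continuing_reduction Proportions in \[0, 1\].
#'   Vectorized.
#' @return A list with components \code{initiates_prevented},
#'   \code{continuing_prevented} and \code{total_prevented}.
#' @export
users_prevented <- function(base, initiation_reduction, continuing_reduction) {
  stopifnot(all(initiation_reduction >= 0), all(initiation_reduction <= 1),
            all(continuing_reduction >= 0), all(continuing_reduction <= 1))
  initiates <- base * initiation_reduction
  continuing <- base * (1 - initiation_reduction) * continuing_reduction
  list(initiates_prevented = initiates,
       continuing_prevented = continuing,
       total_prevented = initiates + continuing)
}

#' Relative reduction in current cigar-use prevalence
#'
#' Total users prevented divided by total current users in the cohort. Must be
#' fed the unrounded chain: the published 37.1% is reproduced by full-precision
#' arithmetic (0.37103) but not by rounded intermediates (0.3704).
#'
#' @param total_prevented Persons. Vectorized.
#' @param current_users Persons (> 0).
#' @return Proportion of current use prevented.
#' @export
prevalence_reduction <- function(total_prevented, current_users) {
  if (any(current_users <= 0)) {
    stop("current_users must be positive", call. = FALSE)
  }
  total_prevented / current_users
}

#' @export
point_estimate.initiation_scenario <- function(scenario) {
  current_users <- scenario$cohort_size * scenario$current_use_prevalence
  base <- flavored_initiate_base(scenario$cohort_size,
                                 scenario$current_use_prevalence,
                                 scenario$flavored_initiation_fraction)
  prevented <- users_prevented(base,
                               scenario$initiation_reduction$mode,
                               scenario$continuing_reduction$mode)
  c(list(current_users = current_users, flavored_base = base),
    prevented,
    list(prevalence_reduction = prevalence_reduction(prevented$total_prevented,
                                                     current_users)))
}

#' @export
eval_model.initiation_scenario <- function(scenario, draws) {
  base <- flavored_initiate_base(scenario$cohort_size,
                                 scenario$current_use_prevalence,
                                 scenario$flavored_initiation_fraction)
  prevented <- users_prevented(base, draws$initiation_reduction,
                               draws$continuing_reduction)
  # primary channel first
  list(total_prevented = prevented$total_prevented,
       initiates_prevented = prevented$initiates_prevented,
       continuing_prevented = prevented$continuing_prevented)
}
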