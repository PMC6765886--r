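#' Specification for a family of synthetic scenarios
#'
#' Describes how to draw random, structurally valid scenarios whose expected
#' primary output is known in closed form (via the independence factorization
#' in \code{\link{analytic_expectation}}). These stand in for external data so
#' the whole pipeline — construction, validation, I/O round-trips, the Monte
#' Carlo engine — is testable against analytic truth.
#'
#' @param seed Integer seed for the generator.
#' @param n_scenarios Number of scenarios to draw (>= 1).
#' @param model_kind \code{"mortality"}, \code{"initiation"} or \code{"both"}
#'   (alternating).
#' @param deaths_range Range for attributable deaths (mortality scenarios).
#' @param cohort_range Range for cohort size (initiation scenarios).
#' @param prevalence_range,flavored_fraction_range Ranges for the initiation
#'   point inputs.
#' @param ratio_range Range (> 1) for the continuing-use prevalence ratio; the
#'   continuing-reduction mode is derived as 1 - 1/ratio and its min/max drawn
#'   around it.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1L, n_scenarios = 50L,
                           model_kind = c("both", "mortality", "initiation"),
                           deaths_range = c(100, 20000),
                           cohort_range = c(1e5, 1e7),
                           prevalence_range = c(0.01, 0.30),
                           flavored_fraction_range = c(0.20, 1.00),
                           ratio_range = c(1.05, 3.00)) {
  model_kind <- match.arg(model_kind)
  stopifnot(n_scenarios >= 1, ratio_range[1] > 1)
  structure(list(seed = as.integer(seed), n_scenarios = as.integer(n_scenarios),
                 model_kind = model_kind, deaths_range = deaths_range,
                 cohort_range = cohort_range, prevalence_range = prevalence_range,
                 flavored_fraction_range = flavored_fraction_range,
                 ratio_range = ratio_range),
            class = "synthetic_spec")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# Random triangular proportion: three sorted uniforms on [lo, hi].
random_triangular <- function(lo = 0, hi = 1) {
  v <- sort(stats::runif(3, lo, hi))
  triangular(v[1], v[2], v[3])
}

#' Generate random scenarios with known expected outputs
#'
#' Each generated scenario passes \code{\link{validate_scenario}} by
#' construction and is paired with its closed-form expected primary output,
#' enabling engine-vs-analytic property tests (the core parameter-recovery
#' surface).
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A list of length \code{n_scenarios}; each element is a list with
#'   components \code{scenario} and \code{expectation}.
#' @export
generate_scenarios <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  kinds <- switch(spec$model_kind,
                  mortality = rep("mortality", spec$n_scenarios),
                  initiation = rep("initiation", spec$n_scenarios),
                  both = rep(c("mortality", "initiation"),
                             length.out = spec$n_scenarios))
  with_seed(spec$seed, lapply(kinds, function(kind) {
    scenario <- if (kind == "mortality") {
      mortality_scenario(
        attributable_deaths = runif1(spec$deaths_range),
        consumption_reduction = random_triangular(),
        cessation_fraction = random_triangular(),
        machine_made_share = stats::runif(1),
        flavored_retail_share = stats::runif(1))
    } else {
      ratio <- runif1(spec$ratio_range)
      mode <- continuing_reduction_from_ratio(ratio)
      initiation_scenario(
        cohort_size = runif1(spec$cohort_range),
        current_use_prevalence = runif1(spec$prevalence_range),
        flavored_initiation_fraction = runif1(spec$flavored_fraction_range),
        initiation_reduction = random_triangular(),
        continuing_prevalence_ratio = ratio,
        continuing_reduction = triangular(stats::runif(1, 0, mode), mode,
                                          stats::runif(1, mode, 1)))
    }
    list(scenario = scenario, expectation = analytic_expectation(scenario))
  }))
}

#' Write synthetic scenarios to disk with an expectation manifest
#'
#' Writes one YAML scenario file per generated scenario plus a
#' \code{manifest.csv} pairing each file with its model kind and closed-form
#' expected primary output.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param out_dir Output directory (created if absent).
#' @return The manifest as a data frame, invisibly.
#' @export
write_synthetic <- function(spec, out_dir) {
  generated <- generate_scenarios(spec)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- lapply(seq_along(generated), function(i) {
    g <- generated[[i]]
    kind <- if (inherits(g$scenario, "mortality_scenario")) "mortality" else "initiation"
    fname <- sprintf("synthetic_%03d_%s.yaml", i, kind)
    write_scenario(g$scenario, file.path(out_dir, fname))
    data.frame(file = fname, model_kind = kind, expectation = g$expectation,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
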