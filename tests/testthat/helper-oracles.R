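# Independent oracles used across test files.

# Rejection sampler for a triangular distribution: independent of the
# inverse-CDF route the package uses.
rtri_reject <- function(n, dist) {
  a <- dist$minimum; b <- dist$mode; c <- dist$maximum
  if (a == c) return(rep(a, n))
  fmax <- 2 / (c - a)
  dens <- function(x) {
    ifelse(x < b, if (b > a) 2 * (x - a) / ((c - a) * (b - a)) else 0,
           if (c > b) 2 * (c - x) / ((c - a) * (c - b)) else 0)
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, a, c)
    keep <- runif(2 * n, 0, fmax) < dens(x)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

published_mortality <- function() mortality_scenario()
published_initiation <- function() initiation_scenario()

# Brute-force draws of each model's primary output, via the rejection sampler.
brute_force_outputs <- function(scenario, n) {
  dists <- scenario_distributions_for_test(scenario)
  draws <- lapply(dists, function(d) rtri_reject(n, d))
  if (inherits(scenario, "mortality_scenario")) {
    scenario$attributable_deaths * draws[[1]] * draws[[2]]
  } else {
    base <- scenario$cohort_size * scenario$current_use_prevalence *
      scenario$flavored_initiation_fraction
    base * (draws[[1]] + (1 - draws[[1]]) * draws[[2]])
  }
}

# Test-local copy of the scenario's uncertain inputs (the package's accessor
# is internal by design).
scenario_distributions_for_test <- function(scenario) {
  if (inherits(scenario, "mortality_scenario")) {
    list(scenario$consumption_reduction, scenario$cessation_fraction)
  } else {
    list(scenario$initiation_reduction, scenario$continuing_reduction)
  }
}
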