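#' Load a scenario configuration file
#'
#' Reads a YAML scenario file declaring a \code{model_kind} of
#' \code{"mortality"} or \code{"initiation"}, its named point inputs and
#' triangular triples (three-element \code{[min, mode, max]} lists), and
#' optional simulation settings. Missing files, unparseable files, missing
#' keys and invariant violations raise distinct error classes
#' (\code{flavorsim_io_error}, \code{flavorsim_parse_error}, and the
#' validation errors of \code{\link{validate_scenario}}); validation failures
#' enumerate every offending key.
#'
#' @param path Path to a YAML scenario file. The two published analyses ship
#'   as fixtures: \code{system.file("extdata", "mortality.yaml",
#'   package = "flavorsim")} and \code{.../initiation.yaml}.
#' @return A list with components \code{scenario} (validated) and
#'   \code{settings} (a \code{\link{sim_settings}}).
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    stop(structure(class = c("flavorsim_io_error", "error", "condition"),
                   list(message = sprintf("scenario file not found: %s", path),
                        call = NULL)))
  }
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(structure(class = c("flavorsim_parse_error", "error", "condition"),
                   list(message = sprintf("cannot parse '%s': %s", path,
                                          conditionMessage(e)),
                        call = NULL)))
  })
  kind <- cfg$model_kind
  if (is.null(kind) || !kind %in% c("mortality", "initiation")) {
    stop(structure(class = c("flavorsim_parse_error", "error", "condition"),
                   list(message = "model_kind must be 'mortality' or 'initiation'",
                        call = NULL)))
  }
  required <- if (kind == "mortality") {
    c("attributable_deaths", "consumption_reduction", "cessation_fraction",
      "machine_made_share", "flavored_retail_share")
  } else {
    c("cohort_size", "current_use_prevalence", "flavored_initiation_fraction",
      "initiation_reduction", "continuing_prevalence_ratio",
      "continuing_reduction")
  }
  missing <- setdiff(required, names(cfg$inputs))
  if (length(missing)) {
    stop(structure(class = c("flavorsim_parse_error", "error", "condition"),
                   list(message = paste0("missing required inputs: ",
                                         paste(missing, collapse = ", ")),
                        call = NULL)))
  }
  parse_tri <- function(v, key) {
    if (!is.numeric(unlist(v)) || length(unlist(v)) != 3L) {
      stop(structure(class = c("flavorsim_parse_error", "error", "condition"),
                     list(message = sprintf(
                       "%s: triangular inputs must be [min, mode, max] triples", key),
                       call = NULL)))
    }
    v <- as.numeric(unlist(v))
    tryCatch(triangular(v[1], v[2], v[3]), error = function(e) {
      stop("invalid scenario:\n  - ", key, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inp <- cfg$inputs
  scenario <- if (kind == "mortality") {
    mortality_scenario(
      attributable_deaths = inp$attributable_deaths,
      consumption_reduction = parse_tri(inp$consumption_reduction,
                                        "consumption_reduction"),
      cessation_fraction = parse_tri(inp$cessation_fraction, "cessation_fraction"),
      machine_made_share = inp$machine_made_share,
      flavored_retail_share = inp$flavored_retail_share)
  } else {
    initiation_scenario(
      cohort_size = inp$cohort_size,
      current_use_prevalence = inp$current_use_prevalence,
      flavored_initiation_fraction = inp$flavored_initiation_fraction,
      initiation_reduction = parse_tri(inp$initiation_reduction,
                                       "initiation_reduction"),
      continuing_prevalence_ratio = inp$continuing_prevalence_ratio,
      continuing_reduction = parse_tri(inp$continuing_reduction,
                                       "continuing_reduction"))
  }
  st <- cfg$settings
  settings <- sim_settings(
    n_iterations = if (is.null(st$n_iterations)) 1000 else st$n_iterations,
    seed = st$seed,
    interval_mass = if (is.null(st$interval_mass)) 0.90 else st$interval_mass)
  list(scenario = scenario, settings = settings)
}

#' Write a scenario configuration file
#'
#' Inverse of \code{\link{load_scenario}}: round-trips field for field.
#'
#' @param scenario A scenario object.
#' @param path Output file path.
#' @param settings Optional \code{\link{sim_settings}} to embed.
#' @return \code{path}, invisibly.
#' @export
write_scenario <- function(scenario, path, settings = NULL) {
  validate_scenario(scenario)
  kind <- if (inherits(scenario, "mortality_scenario")) "mortality" else "initiation"
  as_cfg <- function(v) {
    if (is_triangular(v)) c(v$minimum, v$mode, v$maximum) else v
  }
  cfg <- list(model_kind = kind,
              inputs = lapply(unclass(scenario), as_cfg))
  if (!is.null(settings)) {
    cfg$settings <- list(n_iterations = settings$n_iterations,
                         seed = settings$seed,
                         interval_mass = settings$interval_mass)
    cfg$settings <- Filter(Negate(is.null), cfg$settings)
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

round_persons <- function(x) round(x / 1000) * 1000
round_deaths <- function(x) round(x)
round_pct <- function(p) round(100 * p, 1)

scenario_hash <- function(scenario) {
  flat <- unlist(lapply(unclass(scenario), function(v) {
    if (is_triangular(v)) c(v$minimum, v$mode, v$maximum) else v
  }))
  # order-sensitive rolling hash of the numeric field values; provenance only
  sprintf("%08x", sum(as.integer(
    (abs(flat * 1e6) %% 2147483647) * seq_along(flat)) %% 2147483647L))
}

#' Render analysis reports
#'
#' Writes a human-readable summary (\code{<prefix>_summary.txt}) echoing the
#' headline estimates, and a machine-readable CSV
#' (\code{<prefix>_results.csv}) of the point estimate, simulation mean,
#' prediction-interval bounds and tornado ranges. Rounding (persons to the
#' nearest 1,000, deaths to the nearest death, percentages to one decimal)
#' happens only in the text summary; the CSV keeps full precision. Report
#' headers record seed, iterations, package version and a scenario hash for
#' provenance.
#'
#' @param result A \code{\link{run_simulation}} result.
#' @param tornado_table Output of \code{\link{tornado}}.
#' @param out_dir Output directory (created if absent).
#' @param prefix File-name prefix, e.g. \code{"mortality"}.
#' @return Named character vector of the written file paths, invisibly.
#' @export
render_report <- function(result, tornado_table, out_dir, prefix) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop(structure(class = c("flavorsim_io_error", "error", "condition"),
                     list(message = sprintf("cannot create output directory: %s",
                                            out_dir),
                          call = NULL)))
    }
  }
  scenario <- result$scenario
  pt <- point_estimate(scenario)
  settings <- result$settings
  mass_pct <- 100 * settings$interval_mass
  header <- c(
    sprintf("# flavorsim %s", as.character(utils::packageVersion("flavorsim"))),
    sprintf("# scenario hash: %s", scenario_hash(scenario)),
    sprintf("# iterations: %d  seed: %s  interval mass: %g%%",
            settings$n_iterations,
            if (is.null(settings$seed)) "none" else settings$seed, mass_pct))

  is_mort <- inherits(scenario, "mortality_scenario")
  lines <- header
  if (is_mort) {
    lines <- c(lines, "",
      "Mortality benefit from increased cessation among current exclusive cigar smokers",
      sprintf("  Point estimate: %d premature deaths avoided per year (%d x %g%% x %g%%).",
              round_deaths(pt$deaths_avoided), scenario$attributable_deaths,
              100 * scenario$consumption_reduction$mode,
              100 * scenario$cessation_fraction$mode),
      sprintf("  Simulation mean: %d deaths avoided, %g%% prediction interval %d to %d.",
              round_deaths(result$mean), mass_pct,
              round_deaths(result$interval_low), round_deaths(result$interval_high)))
  } else {
    lines <- c(lines, "",
      "Reduction in cigar use from deterred initiation and continuation (one cohort of 18 year olds)",
      sprintf("  Flavored-initiate base: %s current users who initiated with a flavored product.",
              format(round_persons(pt$flavored_base), big.mark = ",", scientific = FALSE)),
      sprintf("  Initiates prevented: %s; continuing users prevented: %s; total: %s.",
              format(round_persons(pt$initiates_prevented), big.mark = ","),
              format(round_persons(pt$continuing_prevented), big.mark = ","),
              format(round_persons(pt$total_prevented), big.mark = ",")),
      sprintf("  Relative prevalence reduction: %.1f%% of current cigar users in the cohort.",
              round_pct(pt$prevalence_reduction)),
      sprintf("  Simulation mean: %s users prevented, %g%% prediction interval %s to %s.",
              format(round_persons(result$mean), big.mark = ","), mass_pct,
              format(round_persons(result$interval_low), big.mark = ","),
              format(round_persons(result$interval_high), big.mark = ",")))
  }
  lines <- c(lines, "", "One-way sensitivity (conditional bin means and one-at-a-time):")
  fmt_val <- if (is_mort) {
    function(x) format(round_deaths(x), big.mark = ",")
  } else {
    function(x) format(round_persons(x), big.mark = ",")
  }
  for (i in seq_len(nrow(tornado_table))) {
    r <- tornado_table[i, ]
    lines <- c(lines, sprintf("  %s [%s]: %s to %s", r$input_name, r$method,
                              fmt_val(r$low), fmt_val(r$high)))
  }

  txt_path <- file.path(out_dir, paste0(prefix, "_summary.txt"))
  writeLines(lines, txt_path)

  primary_point <- if (is_mort) pt$deaths_avoided else pt$total_prevented
  summary_df <- data.frame(
    quantity = c("point_estimate", "simulation_mean", "interval_low", "interval_high"),
    value = c(primary_point, result$mean, result$interval_low, result$interval_high))
  csv_path <- file.path(out_dir, paste0(prefix, "_results.csv"))
  utils::write.csv(summary_df, csv_path, row.names = FALSE)
  tornado_path <- file.path(out_dir, paste0(prefix, "_tornado.csv"))
  utils::write.csv(tornado_table, tornado_path, row.names = FALSE)

  invisible(c(summary = txt_path, results = csv_path, tornado = tornado_path))
}

#' Reproduce the published analyses end to end
#'
#' Loads the two bundled scenario fixtures, computes the deterministic point
#' estimates, runs both Monte Carlo simulations, both tornado sensitivity
#' analyses, and writes all reports.
#'
#' @param out_dir Directory for the report files.
#' @param seed Integer seed for both simulations.
#' @param n_iterations Iterations per simulation (default 1000, as published;
#'   increase for stabler interval bounds).
#' @param n_bins Bins for the conditional-mean tornado (default deciles).
#' @return A list with the two \code{simulation_result}s, tornado tables and
#'   written file paths, invisibly.
#' @export
reproduce_analysis <- function(out_dir, seed = 1L, n_iterations = 1000, n_bins = 10) {
  fixtures <- c(mortality = "mortality.yaml", initiation = "initiation.yaml")
  res <- lapply(names(fixtures), function(nm) {
    path <- system.file("extdata", fixtures[[nm]], package = "flavorsim")
    loaded <- load_scenario(path)
    settings <- sim_settings(n_iterations = n_iterations, seed = seed,
                             interval_mass = loaded$settings$interval_mass)
    sim <- run_simulation(loaded$scenario, settings)
    tor <- tornado(sim, n_bins = n_bins)
    files <- render_report(sim, tor, out_dir, nm)
    list(simulation = sim, tornado = tor, files = files)
  })
  names(res) <- names(fixtures)
  invisible(res)
}
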