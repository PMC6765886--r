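test_that("empirical quantile interpolates linearly on order statistics", {
  expect_equal(empirical_quantile(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(empirical_quantile(c(0, 10), 0.25), 2.5)
  expect_equal(empirical_quantile(rep(7, 20), c(0, 0.3, 1)), rep(7, 3))
  x <- c(4, 1, 9, 2)
  expect_equal(empirical_quantile(x, 0), min(x))
  expect_equal(empirical_quantile(x, 1), max(x))
  expect_error(empirical_quantile(numeric(0), 0.5), "non-empty")
  expect_error(empirical_quantile(1:3, 1.2), "\\[0, 1\\]")
})

test_that("degenerate inputs collapse the simulation to the point estimate", {
  s <- mortality_scenario(consumption_reduction = triangular(0.30, 0.30, 0.30),
                          cessation_fraction = triangular(0.50, 0.50, 0.50))
  res <- run_simulation(s, sim_settings(200, seed = 5))
  expect_equal(res$mean, 780)
  expect_equal(res$interval_low, 780)
  expect_equal(res$interval_high, 780)
  expect_true(all(res$outputs$deaths_avoided == 780))
})

test_that("same seed gives bit-identical results; different seeds differ", {
  s <- mortality_scenario()
  r1 <- run_simulation(s, sim_settings(500, seed = 42))
  r2 <- run_simulation(s, sim_settings(500, seed = 42))
  expect_identical(r1, r2)
  r3 <- run_simulation(s, sim_settings(500, seed = 43))
  expect_false(identical(r1$outputs, r3$outputs))
})

test_that("seeded runs do not disturb the caller's random stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(run_simulation(mortality_scenario(), sim_settings(100, seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("retained draws and outputs have one value per iteration", {
  res <- run_simulation(initiation_scenario(), sim_settings(321, seed = 8))
  expect_equal(lengths(res$draws), c(initiation_reduction = 321L,
                                     continuing_reduction = 321L))
  expect_true(all(lengths(res$outputs) == 321L))
  expect_equal(res$primary_output, "total_prevented")
})

test_that("prediction interval holds at least its nominal mass", {
  for (seed in 1:5) {
    res <- run_simulation(mortality_scenario(), sim_settings(2000, seed = seed))
    y <- res$outputs$deaths_avoided
    covered <- mean(y >= res$interval_low & y <= res$interval_high)
    expect_gte(covered, res$settings$interval_mass - 2 / length(y))
    expect_lte(res$interval_low, res$mean)
    expect_lte(res$mean, res$interval_high)
  }
})

test_that("large-n mean and quantiles agree with a brute-force oracle", {
  n <- 1e5
  for (make in list(published_mortality, published_initiation)) {
    s <- make()
    res <- run_simulation(s, sim_settings(n, seed = 77))
    mu <- analytic_expectation(s)
    # mean within 4 standard errors of the analytic expectation
    se <- sd(res$outputs[[1]]) / sqrt(n)
    expect_lt(abs(res$mean - mu), 4 * se)
    # quantiles against an independent rejection-sampling oracle
    set.seed(1234)
    oracle <- brute_force_outputs(s, 2e5)
    for (q in c(0.05, 0.5, 0.95)) {
      expect_equal(empirical_quantile(res$outputs[[1]], q),
                   empirical_quantile(oracle, q),
                   tolerance = 0.02)
    }
  }
})

test_that("invalid scenarios and settings are rejected before running", {
  s <- mortality_scenario()
  s$attributable_deaths <- -1 # corrupted after construction
  expect_error(run_simulation(s, sim_settings(10, seed = 1)),
               "attributable_deaths")
  expect_error(sim_settings(0), "n_iterations")
  expect_error(sim_settings(100, interval_mass = 1))
})
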