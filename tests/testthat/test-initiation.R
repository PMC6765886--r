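test_that("continuing-use reduction follows 1 - 1/prevalence-ratio", {
  expect_equal(round(continuing_reduction_from_ratio(1.56), 3), 0.359)
  expect_equal(continuing_reduction_from_ratio(1.0), 0)
  expect_equal(continuing_reduction_from_ratio(1.29), 0.2248, tolerance = 1e-3)
  expect_error(continuing_reduction_from_ratio(0), "positive")
  expect_error(continuing_reduction_from_ratio(-2), "positive")
})

test_that("flavored-initiate base is the unrounded triple product", {
  expect_equal(flavored_initiate_base(4.2e6, 0.072, 0.654), 197769.6)
  expect_equal(flavored_initiate_base(4.2e6, 0.072, 1.0), 302400)
  expect_equal(flavored_initiate_base(0, 0.5, 0.5), 0)
})

test_that("deterrence routes partition the base and sum correctly", {
  base <- 197769.6
  p <- users_prevented(base, 0.325, continuing_reduction_from_ratio(1.56))
  expect_equal(p$initiates_prevented, 64275.12, tolerance = 1e-8)
  expect_equal(p$continuing_prevented, 47921.095, tolerance = 1e-7)
  expect_equal(p$total_prevented, p$initiates_prevented + p$continuing_prevented)
  # full deterrence leaves no initiates to continue
  p1 <- users_prevented(base, 1.0, 0.4)
  expect_equal(p1$initiates_prevented, base)
  expect_equal(p1$continuing_prevented, 0)
  expect_equal(p1$total_prevented, base)
  p0 <- users_prevented(base, 0, 0)
  expect_equal(unlist(p0), c(initiates_prevented = 0, continuing_prevented = 0,
                             total_prevented = 0))
})

test_that("total prevented never exceeds the base and increases in both inputs", {
  set.seed(21)
  for (i in 1:25) {
    base <- runif(1, 1e3, 1e6)
    d <- runif(1); c <- runif(1)
    tot <- users_prevented(base, d, c)$total_prevented
    expect_lte(tot, base + 1e-9)
    eps <- 0.01
    if (d + eps <= 1) {
      expect_gte(users_prevented(base, d + eps, c)$total_prevented, tot)
    }
    if (c + eps <= 1) {
      expect_gte(users_prevented(base, d, c + eps)$total_prevented, tot)
    }
  }
})

test_that("prevalence reduction needs the unrounded chain to hit one decimal", {
  expect_equal(round(100 * prevalence_reduction(112197.7, 302400), 1), 37.1)
  # rounded intermediates land on a different second decimal
  expect_equal(round(100 * prevalence_reduction(112000, 302400), 2), 37.04)
  expect_equal(prevalence_reduction(0, 302400), 0)
  expect_error(prevalence_reduction(100, 0), "positive")
})

test_that("initiation point estimate reproduces the published chain unrounded", {
  pt <- point_estimate(initiation_scenario())
  expect_equal(pt$current_users, 302400)
  expect_equal(pt$flavored_base, 197769.6)
  expect_equal(round(pt$initiates_prevented / 1000) * 1000, 64000)
  expect_equal(round(pt$continuing_prevented / 1000) * 1000, 48000)
  expect_equal(round(pt$total_prevented / 1000) * 1000, 112000)
  expect_equal(round(100 * pt$prevalence_reduction, 1), 37.1)
})

test_that("initiation scenario validation checks the ratio-mode consistency", {
  expect_error(
    initiation_scenario(continuing_prevalence_ratio = 2.0),
    "1 - 1/prevalence ratio")
  # consistent pair passes
  s <- initiation_scenario(continuing_prevalence_ratio = 2.0,
                           continuing_reduction = triangular(0.3, 0.5, 0.7))
  expect_s3_class(s, "initiation_scenario")
  err <- tryCatch(
    initiation_scenario(cohort_size = 0, current_use_prevalence = 2),
    error = function(e) conditionMessage(e))
  expect_match(err, "cohort_size")
  expect_match(err, "current_use_prevalence")
})
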