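test_that("constructor enforces parameter ordering and permits point masses", {
  d <- triangular(0.15, 0.30, 0.45)
  expect_s3_class(d, "triangular")
  expect_error(triangular(0.5, 0.4, 0.6), "minimum <= mode <= maximum")
  expect_error(triangular(0.1, 0.3, 0.2), "minimum <= mode <= maximum")
  expect_error(triangular(NA_real_, 0.3, 0.4), "finite")
  point <- triangular(0.5, 0.5, 0.5)
  expect_identical(tri_mean(point), 0.5)
  expect_identical(tri_var(point), 0)
})

test_that("mean and variance follow the closed forms", {
  expect_equal(tri_mean(triangular(0.15, 0.30, 0.45)), 0.30)
  expect_equal(tri_mean(triangular(0.225, 0.359, 0.465)), 0.349667, tolerance = 1e-6)
  d <- triangular(0.25, 0.50, 0.75)
  a <- 0.25; b <- 0.50; c <- 0.75
  expect_equal(tri_var(d), (a^2 + b^2 + c^2 - a * b - a * c - b * c) / 18)
})

test_that("quantile function matches hand-solved values and support endpoints", {
  d <- triangular(0.15, 0.30, 0.45)
  expect_equal(tri_ppf(0, d), 0.15)
  expect_equal(tri_ppf(1, d), 0.45)
  expect_equal(tri_ppf(0.5, d), 0.30) # symmetric: median = mode
  # solve (x - 0.25)^2 / ((0.75 - 0.25)(0.50 - 0.25)) = 0.1
  expect_equal(tri_ppf(0.1, triangular(0.25, 0.50, 0.75)), 0.3618034,
               tolerance = 1e-6)
  expect_error(tri_ppf(-0.01, d), "\\[0, 1\\]")
  expect_error(tri_ppf(1.01, d), "\\[0, 1\\]")
  point <- triangular(0.3, 0.3, 0.3)
  expect_equal(tri_ppf(c(0, 0.37, 1), point), rep(0.3, 3))
})

test_that("quantile function is non-decreasing and inverts the CDF", {
  dists <- list(triangular(0.15, 0.30, 0.45),
                triangular(0, 0.325, 0.65),        # mode interior, min at 0
                triangular(0.2, 0.2, 0.9),         # mode at minimum
                triangular(0.1, 0.8, 0.8),         # mode at maximum
                triangular(0.225, 0.359, 0.465))
  u <- seq(0, 1, by = 0.01)
  for (d in dists) {
    q <- tri_ppf(u, d)
    expect_true(all(diff(q) >= -1e-12))
    x <- seq(d$minimum + 1e-9, d$maximum - 1e-9, length.out = 101)
    expect_equal(tri_ppf(tri_cdf(x, d), d), x, tolerance = 1e-8)
  }
})

test_that("sampling is seed-reproducible and matches the closed-form moments", {
  d <- triangular(0.15, 0.30, 0.45)
  set.seed(101); s1 <- tri_sample(d, 1000)
  set.seed(101); s2 <- tri_sample(d, 1000)
  expect_identical(s1, s2)

  set.seed(202)
  n <- 2e5
  for (d in list(triangular(0.15, 0.30, 0.45), triangular(0, 0.325, 0.65),
                 triangular(0.225, 0.359, 0.465))) {
    s <- tri_sample(d, n)
    se_mean <- sqrt(tri_var(d) / n)
    expect_lt(abs(mean(s) - tri_mean(d)), 4 * se_mean)
    # variance: 4-sigma CLT bound using the empirical variance of (x - mean)^2
    se_var <- sd((s - tri_mean(d))^2) / sqrt(n)
    expect_lt(abs(var(s) - tri_var(d)), 4 * se_var)
    expect_true(all(s >= d$minimum & s <= d$maximum))
  }
  expect_equal(tri_sample(triangular(0.3, 0.3, 0.3), 5), rep(0.3, 5))
  expect_error(tri_sample(d, 0), "positive count")
})

test_that("sampler agrees in distribution with an independent rejection sampler", {
  set.seed(33)
  d <- triangular(0, 0.325, 0.65)
  a <- tri_sample(d, 4e4)
  b <- rtri_reject(4e4, d)
  ks <- suppressWarnings(ks.test(a, b))
  expect_gt(ks$p.value, 1e-4)
})

test_that("conditional slice means match numeric integration of x f(x)", {
  dists <- list(triangular(0.15, 0.30, 0.45), triangular(0, 0.325, 0.65),
                triangular(0.2, 0.2, 0.9), triangular(0.1, 0.8, 0.8))
  for (d in dists) {
    dens <- function(x) {
      a <- d$minimum; b <- d$mode; c <- d$maximum
      ifelse(x < b, if (b > a) 2 * (x - a) / ((c - a) * (b - a)) else 0,
             if (c > b) 2 * (c - x) / ((c - a) * (c - b)) else 0)
    }
    for (slice in list(c(0, 0.1), c(0.9, 1), c(0.3, 0.7), c(0, 1))) {
      lo <- tri_ppf(slice[1], d); hi <- tri_ppf(slice[2], d)
      num <- integrate(function(x) x * dens(x), lo, hi,
                       rel.tol = 1e-10)$value / (slice[2] - slice[1])
      expect_equal(tri_bin_mean(d, slice[1], slice[2]), num, tolerance = 1e-6)
    }
  }
  # whole-support slice recovers the mean; point mass returns the mass point
  expect_equal(tri_bin_mean(triangular(0.15, 0.3, 0.45), 0, 1), 0.30)
  expect_equal(tri_bin_mean(triangular(0.4, 0.4, 0.4), 0, 0.5), 0.4)
})
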