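#' Triangular distribution
#'
#' Constructor for the three-parameter triangular distribution used to encode
#' expert uncertainty about every stochastic model input: a minimum, a most
#' likely value (mode), and a maximum. The degenerate case
#' \code{minimum == mode == maximum} is allowed and represents a point mass,
#' so deterministic and Monte Carlo runs share one code path.
#'
#' @param minimum Lower bound of the support.
#' @param mode Most likely value; must satisfy \code{minimum <= mode <= maximum}.
#' @param maximum Upper bound of the support.
#' @return An object of class \code{triangular}.
#' @examples
#' triangular(0.15, 0.30, 0.45)
#' triangular(0.5, 0.5, 0.5) # point mass
#' @export
triangular <- function(minimum, mode, maximum) {
  stopifnot(is.numeric(minimum), is.numeric(mode), is.numeric(maximum),
            length(minimum) == 1L, length(mode) == 1L, length(maximum) == 1L)
  if (any(!is.finite(c(minimum, mode, maximum)))) {
    stop("triangular parameters must be finite", call. = FALSE)
  }
  if (minimum > mode || mode > maximum) {
    stop(sprintf("triangular parameters must satisfy minimum <= mode <= maximum, got (%g, %g, %g)",
                 minimum, mode, maximum), call. = FALSE)
  }
  structure(list(minimum = minimum, mode = mode, maximum = maximum),
            class = "triangular")
}

#' @export
print.triangular <- function(x, ...) {
  cat(sprintf("Triangular(min = %g, mode = %g, max = %g)\n",
              x$minimum, x$mode, x$maximum))
  invisible(x)
}

is_triangular <- function(x) inherits(x, "triangular")

is_degenerate <- function(dist) dist$minimum == dist$maximum

#' Mean of a triangular distribution
#'
#' @param dist A \code{\link{triangular}} object.
#' @return \code{(minimum + mode + maximum) / 3}.
#' @export
tri_mean <- function(dist) {
  stopifnot(is_triangular(dist))
  (dist$minimum + dist$mode + dist$maximum) / 3
}

#' Variance of a triangular distribution
#'
#' @param dist A \code{\link{triangular}} object.
#' @return \code{(a^2 + b^2 + c^2 - ab - ac - bc) / 18} for parameters (a, b, c).
#' @export
tri_var <- function(dist) {
  stopifnot(is_triangular(dist))
  a <- dist$minimum; b <- dist$mode; c <- dist$maximum
  (a^2 + b^2 + c^2 - a * b - a * c - b * c) / 18
}

#' Triangular cumulative distribution function
#'
#' @param x Vector of evaluation points.
#' @param dist A \code{\link{triangular}} object.
#' @return P(X <= x). For a point mass, a step function at the mass point.
#' @export
tri_cdf <- function(x, dist) {
  stopifnot(is_triangular(dist), is.numeric(x))
  a <- dist$minimum; b <- dist$mode; c <- dist$maximum
  if (is_degenerate(dist)) return(as.numeric(x >= a))
  p <- numeric(length(x))
  left <- x > a & x < b
  right <- x >= b & x < c
  if (b > a) p[left] <- (x[left] - a)^2 / ((c - a) * (b - a))
  # x == b handled by the right branch; if b == a the left branch is empty
  p[right] <- 1 - (c - x[right])^2 / ((c - a) * (c - b))
  if (b == c) p[x >= b] <- 1
  p[x >= c] <- 1
  p
}

#' Triangular quantile function (inverse CDF)
#'
#' Piecewise square-root inverse of the triangular CDF. For a degenerate
#' (point-mass) distribution every quantile is the mass point.
#'
#' @param u Vector of probabilities in \[0, 1\].
#' @param dist A \code{\link{triangular}} object.
#' @return The u-quantiles of \code{dist}.
#' @export
tri_ppf <- function(u, dist) {
  stopifnot(is_triangular(dist), is.numeric(u))
  if (any(u < 0 | u > 1, na.rm = TRUE) || anyNA(u)) {
    stop("quantile levels must lie in [0, 1]", call. = FALSE)
  }
  a <- dist$minimum; b <- dist$mode; c <- dist$maximum
  if (is_degenerate(dist)) return(rep(a, length(u)))
  f_mode <- (b - a) / (c - a)
  x <- numeric(length(u))
  lo <- u <= f_mode
  x[lo] <- a + sqrt(u[lo] * (c - a) * (b - a))
  x[!lo] <- c - sqrt((1 - u[!lo]) * (c - a) * (c - b))
  x
}

#' Sample from a triangular distribution
#'
#' Inverse-CDF transform of a single uniform stream drawn from R's current
#' random number generator, so runs are reproducible from one seed and each
#' draw maps one-to-one to a uniform variate.
#'
#' @param dist A \code{\link{triangular}} object.
#' @param n Number of draws (>= 1).
#' @return Numeric vector of \code{n} independent draws.
#' @export
tri_sample <- function(dist, n) {
  stopifnot(is_triangular(dist))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  tri_ppf(stats::runif(n), dist)
}

#' Conditional mean of a triangular distribution between probability levels
#'
#' Closed-form E\[X | F(p_lo) < X <= F(p_hi)\], i.e. the mean of the
#' distribution restricted to the probability slice \[p_lo, p_hi\]. Used as the
#' analytic counterpart of the binned conditional means in the tornado
#' sensitivity analysis.
#'
#' @param dist A \code{\link{triangular}} object.
#' @param p_lo,p_hi Probability levels with \code{0 <= p_lo < p_hi <= 1}.
#' @return The conditional mean over the slice.
#' @export
tri_bin_mean <- function(dist, p_lo, p_hi) {
  stopifnot(is_triangular(dist), p_lo >= 0, p_hi <= 1, p_lo < p_hi)
  a <- dist$minimum; b <- dist$mode; c <- dist$maximum
  if (is_degenerate(dist)) return(a)
  # Integral of x * f(x) from a to t on each linear branch of the density.
  m1 <- function(t) { # lower branch: f(x) = 2(x - a) / ((c - a)(b - a))
    2 / ((c - a) * (b - a)) * (t^3 / 3 - a * t^2 / 2 - (a^3 / 3 - a^3 / 2))
  }
  m2 <- function(t) { # upper branch: f(x) = 2(c - x) / ((c - a)(c - b))
    2 / ((c - a) * (c - b)) * (c * t^2 / 2 - t^3 / 3 - (c * b^2 / 2 - b^3 / 3))
  }
  partial <- function(t) { # integral of x f(x) over (a, t]
    if (t <= b) {
      if (b == a) 0 else m1(t)
    } else {
      base <- if (b == a) 0 else m1(b)
      base + if (c == b) 0 else m2(min(t, c))
    }
  }
  x_lo <- tri_ppf(p_lo, dist)
  x_hi <- tri_ppf(p_hi, dist)
  (partial(x_hi) - partial(x_lo)) / (p_hi - p_lo)
}
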