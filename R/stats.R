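# Statistical comparisons and density summaries used by the pipeline.
# All tests are two-sided and return a common tidy schema.

test_result <- function(method, statistic, p_value, n1, n2 = 0L) {
  tibble(method = method, statistic = unname(statistic),
         p_value = unname(p_value), n1 = n1, n2 = n2, tails = "two")
}

check_sample <- function(x, name, min_n = 2L) {
  if (!is.numeric(x)) stop_param(sprintf("`%s` must be numeric.", name))
  x <- x[is.finite(x)]
  if (length(x) < min_n) {
    stop_data(sprintf("`%s` needs at least %d finite values.", name, min_n))
  }
  x
}

#' Two-sided variance F-test
#'
#' Tests equality of variances of two samples with the variance-ratio
#' F-test: `F = var(x) / var(y)` on `(n_x - 1, n_y - 1)` degrees of
#' freedom, two-sided p-value `2 * min(P(F <= f), P(F >= f))`. Swapping
#' the samples gives the reciprocal statistic and the same p-value.
#'
#' @param x,y Numeric samples (>= 2 finite values, nonzero variance each).
#' @return One-row tibble: `method`, `statistic`, `p_value`, `n1`, `n2`,
#'   `tails`.
#' @export
#' @examples
#' f_test_variance(rnorm(30, sd = 2), rnorm(30, sd = 1))
f_test_variance <- function(x, y) {
  x <- check_sample(x, "x")
  y <- check_sample(y, "y")
  if (var(x) == 0 || var(y) == 0) {
    stop_data("Variance F-test requires nonzero variance in both samples.")
  }
  f <- var(x) / var(y)
  d1 <- length(x) - 1L
  d2 <- length(y) - 1L
  # upper tail evaluated as pf(1/f) with swapped df: numerically stable and
  # exactly symmetric under sample swap (f -> 1/f)
  p <- min(1, 2 * min(pf(f, d1, d2), pf(1 / f, d2, d1)))
  test_result("f_variance", f, p, length(x), length(y))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Standard two-sample KS statistic with the asymptotic p-value.
#'
#' @inheritParams f_test_variance
#' @return One-row tibble in the [f_test_variance()] schema.
#' @export
ks_two_sample <- function(x, y) {
  x <- check_sample(x, "x")
  y <- check_sample(y, "y")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  test_result("ks_two_sample", kt$statistic, kt$p.value,
              length(x), length(y))
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample with 3 to 5000 finite values and nonzero
#'   variance.
#' @return One-row tibble in the [f_test_variance()] schema (`n2 = 0`).
#' @export
shapiro_wilk <- function(x) {
  x <- check_sample(x, "x", min_n = 3L)
  if (length(x) > 5000L) {
    stop_data("Shapiro-Wilk supports at most 5000 values.")
  }
  if (var(x) == 0) stop_data("Shapiro-Wilk requires nonzero variance.")
  st <- shapiro.test(x)
  test_result("shapiro_wilk", st$statistic, st$p.value, length(x))
}

#' Gaussian kernel density estimate
#'
#' Kernel density estimate with a Gaussian kernel, evaluated on an
#' arbitrary grid: `f(g) = mean(dnorm(g, x_i, bw))`. The default
#' bandwidth is Silverman's rule of thumb ([stats::bw.nrd0()]); the raw
#' density integrates to ~1 over the default grid. With
#' `normalize_peak = TRUE` the density is rescaled so its maximum is 1
#' (the convention used to overlay distributions for display).
#'
#' @param x Numeric sample (>= 2 finite values, nonzero variance).
#' @param grid Evaluation points; default 512 points spanning the data
#'   plus four bandwidths on each side.
#' @param bandwidth Kernel standard deviation; default Silverman.
#' @param normalize_peak Rescale so `max(density) == 1`.
#'
#' @return A tibble of class `"kde_estimate"` with columns `grid` and
#'   `density`; attributes `bandwidth` and `normalized_to_peak`.
#' @export
#' @examples
#' kde <- gaussian_kde(rnorm(200))
#' attr(kde, "bandwidth")
gaussian_kde <- function(x, grid = NULL, bandwidth = NULL,
                         normalize_peak = FALSE) {
  x <- check_sample(x, "x")
  if (var(x) == 0) stop_data("KDE requires nonzero variance.")
  bw <- bandwidth %||% bw.nrd0(x)
  check_number(bw, "bandwidth", lower = 0, strict_lower = TRUE)
  if (is.null(grid)) {
    grid <- seq(min(x) - 4 * bw, max(x) + 4 * bw, length.out = 512L)
  }
  if (!is.numeric(grid) || length(grid) < 2L || is.unsorted(grid)) {
    stop_param("`grid` must be an increasing numeric vector.")
  }
  dens <- vapply(grid, function(g) mean(dnorm(g, mean = x, sd = bw)),
                 numeric(1))
  if (normalize_peak) dens <- dens / max(dens)
  structure(tibble(grid = grid, density = dens),
            class = c("kde_estimate", class(tibble())),
            bandwidth = bw, normalized_to_peak = normalize_peak)
}

#' Empirical cumulative distribution table
#'
#' Right-continuous empirical CDF evaluated at the sorted unique sample
#' values.
#'
#' @param x Numeric sample (>= 1 finite value).
#' @return Tibble with columns `value` and `cdf` (non-decreasing,
#'   ending at 1).
#' @export
#' @examples
#' ecdf_table(c(1, 2, 3))
ecdf_table <- function(x) {
  x <- check_sample(x, "x", min_n = 1L)
  f <- stats::ecdf(x)
  v <- sort(unique(x))
  tibble(value = v, cdf = f(v))
}
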