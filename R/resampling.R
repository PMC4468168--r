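#' Difference of group medians
#'
#' The test statistic used throughout the package: the median of `a`
#' minus the median of `b` (written Md below). Tolerance-score
#' distributions from thermal assays are typically skewed with unequal
#' variances, which is why inference is built on medians and
#' resampling rather than on means and normal theory.
#'
#' @param a,b Non-empty numeric vectors of finite values.
#' @return A single number, `median(a) - median(b)`. For even-length
#'   vectors the median is the mean of the two middle order statistics.
#' @examples
#' median_diff(c(5.9, 6.2, 6.4), c(0.5, 0.6, 0.8))
#' @export
median_diff <- function(a, b) {
  check_finite_numeric(a, "a")
  check_finite_numeric(b, "b")
  median(a) - median(b)
}

#' Two-sample randomization test on the difference of medians
#'
#' Tests the null hypothesis of exchangeability between two groups using
#' Md = median(a) - median(b) as the test statistic. Null draws
#' re-partition the pooled values into groups of the original sizes
#' without replacement. When the number of distinct partitions is at
#' most `exact_threshold`, all partitions are enumerated and the p-value
#' is exact; otherwise `n_perm` Monte-Carlo partitions are drawn and the
#' add-one estimator p = (1 + #\{|T*| >= |T_obs|\}) / (n_perm + 1) is
#' used, which guarantees p > 0 and a valid test.
#'
#' The two-tailed p-value counts permuted statistics whose absolute
#' value reaches `|T_obs|`, compared with exact floating-point equality;
#' heavy ties therefore make the test conservative (never anti-
#' conservative). Null partitions are generated from the sorted pooled
#' values with the smaller group size drawn first, so swapping `a` and
#' `b` under the same seed gives an identical p-value and a negated Md.
#'
#' @param a,b Numeric vectors with at least 2 observations each.
#' @param n_perm Number of Monte-Carlo permutations (default 100,000).
#' @param seed Optional integer seed for the Monte-Carlo draw; the
#'   caller's RNG state is left untouched.
#' @param exact_threshold Enumerate all partitions exactly when
#'   `choose(n, n_a)` is at most this value (default 1e5).
#' @return An object of class `"perm_test"`: a list with elements
#'   `md_a`, `md_b`, `md_diff`, `p_value`, `n_perm`, `exact`, `seed`,
#'   `n_a`, `n_b`. Use [tidy()] to get a one-row tibble.
#' @examples
#' set.seed(1)
#' randomization_test(rnorm(10, 1), rnorm(10), n_perm = 999, seed = 42)
#' @export
randomization_test <- function(a, b, n_perm = 100000L, seed = NULL,
                               exact_threshold = 100000) {
  check_finite_numeric(a, "a")
  check_finite_numeric(b, "b")
  if (length(a) < 2L || length(b) < 2L) {
    value_error("Both groups need at least 2 observations.")
  }
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1) {
    config_error("`n_perm` must be a positive integer.")
  }
  n_perm <- as.integer(n_perm)

  md_a <- median(a)
  md_b <- median(b)
  obs <- md_a - md_b

  pool <- sort(c(a, b))
  n <- length(pool)
  n_a <- length(a)
  n_b <- length(b)
  k <- min(n_a, n_b)
  n_part <- choose(n, k)

  if (n_part <= exact_threshold) {
    idx <- combn(n, k)
    abs_obs <- abs(obs)
    hits <- 0L
    for (j in seq_len(ncol(idx))) {
      g1 <- pool[idx[, j]]
      g2 <- pool[-idx[, j]]
      if (abs(fast_median(g1) - fast_median(g2)) >= abs_obs) hits <- hits + 1L
    }
    p <- hits / n_part
    res <- list(md_a = md_a, md_b = md_b, md_diff = obs, p_value = p,
                n_perm = as.integer(n_part), exact = TRUE, seed = seed,
                n_a = n_a, n_b = n_b)
    return(structure(res, class = "perm_test"))
  }

  abs_obs <- abs(obs)
  hits <- with_seed(seed, {
    h <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n)
      g1 <- pool[perm[seq_len(k)]]
      g2 <- pool[perm[(k + 1L):n]]
      if (abs(fast_median(g1) - fast_median(g2)) >= abs_obs) h <- h + 1L
    }
    h
  })
  p <- (1 + hits) / (n_perm + 1)
  structure(list(md_a = md_a, md_b = md_b, md_diff = obs, p_value = p,
                 n_perm = n_perm, exact = FALSE, seed = seed,
                 n_a = n_a, n_b = n_b),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Randomization test on difference of medians\n")
  cat(sprintf("  Md_a = %.4g, Md_b = %.4g, Md_diff = %.4g\n",
              x$md_a, x$md_b, x$md_diff))
  cat(sprintf("  p = %.4g (%s, %d %s)\n", x$p_value,
              if (x$exact) "exact" else "Monte-Carlo",
              x$n_perm,
              if (x$exact) "partitions" else "permutations"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    md_a = x$md_a, md_b = x$md_b, md_diff = x$md_diff,
    p_value = x$p_value, n_perm = x$n_perm, exact = x$exact,
    n_a = x$n_a, n_b = x$n_b
  )
}

#' Percentile bootstrap confidence interval for the median
#'
#' Resamples the data with replacement `n_boot` times, computes the
#' median of each resample, and returns the percentile interval at
#' `((1 - level)/2, 1 - (1 - level)/2)` of the resampled medians.
#'
#' @param values Numeric vector with at least 2 observations.
#' @param n_boot Number of bootstrap resamples (default 10,000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param seed Optional integer seed; the caller's RNG state is left
#'   untouched.
#' @return An object of class `"boot_ci"`: a list with `median`,
#'   `lower`, `upper`, `level`, `n_boot`, `seed`. Use [tidy()] for a
#'   one-row tibble.
#' @examples
#' bootstrap_median_ci(rgamma(25, 4), n_boot = 999, seed = 7)
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000L, level = 0.95,
                                seed = NULL) {
  check_finite_numeric(values, "values")
  if (length(values) < 2L) {
    value_error("`values` needs at least 2 observations.")
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    config_error("`level` must be strictly between 0 and 1.")
  }
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 1) {
    config_error("`n_boot` must be a positive integer.")
  }
  n_boot <- as.integer(n_boot)
  n <- length(values)
  meds <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) fast_median(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- unname(quantile(meds, c(alpha, 1 - alpha), names = FALSE))
  structure(list(median = median(values), lower = qs[1], upper = qs[2],
                 level = level, n_boot = n_boot, seed = seed),
            class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("Median %.4g, %g%% percentile bootstrap CI [%.4g, %.4g] (n_boot = %d)\n",
              x$median, 100 * x$level, x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.boot_ci <- function(x, ...) {
  tibble::tibble(median = x$median, lower = x$lower, upper = x$upper,
                 level = x$level, n_boot = x$n_boot)
}
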