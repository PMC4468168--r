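test_that("median_diff reproduces the reference effect sizes", {
  # vectors constructed so group medians equal the published values
  lab_f <- c(6.0, 6.19, 6.4)
  field_f <- c(0.5, 0.62, 0.9)
  expect_equal(median_diff(lab_f, field_f), 5.57)
  lab_m <- c(5.8, 5.92, 6.1, 6.3) # even n: mean of middle pair = 6.01
  expect_equal(median(lab_m), 6.01)
  expect_equal(median_diff(c(5.9, 5.92, 6.0), c(0.7, 0.74, 0.8)), 5.18)
  expect_equal(median_diff(1:5, 1:5), 0)
  expect_error(median_diff(numeric(), 1:3), class = "thermotol_value_error")
})

test_that("identical groups give Md = 0 and p = 1", {
  res <- randomization_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$md_diff, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$exact)
})

test_that("exact enumeration matches an independent brute-force oracle", {
  set.seed(101)
  sizes <- list(c(2, 2), c(3, 3), c(4, 4), c(5, 5), c(4, 6), c(2, 8))
  for (sz in sizes) {
    for (rep in 1:3) {
      a <- round(rgamma(sz[1], 3), 2)
      b <- round(rgamma(sz[2], 3) + rep - 2, 2)
      res <- randomization_test(a, b)
      expect_true(res$exact)
      expect_equal(res$p_value, oracle_perm_p(a, b))
    }
  }
})

test_that("Monte-Carlo p agrees with the exact p within 3 MC standard errors", {
  set.seed(7)
  a <- rnorm(5, 1)
  b <- rnorm(5)
  exact <- randomization_test(a, b)
  expect_true(exact$exact)
  expect_equal(exact$n_perm, choose(10, 5))
  mc <- randomization_test(a, b, n_perm = 20000, seed = 3, exact_threshold = 0)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / mc$n_perm)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1e-4)
})

test_that("swapping the groups negates Md and preserves the p-value", {
  set.seed(11)
  a <- rgamma(7, 2)
  b <- rgamma(12, 2) + 0.4
  r1 <- randomization_test(a, b, n_perm = 2000, seed = 5)
  r2 <- randomization_test(b, a, n_perm = 2000, seed = 5)
  expect_equal(r1$md_diff, -r2$md_diff)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("p-values are bounded away from zero and reach at most 1", {
  a <- 1:25 + 100
  b <- rnorm(25)
  res <- randomization_test(a, b, n_perm = 999, seed = 1, exact_threshold = 0)
  expect_equal(res$p_value, 1 / 1000) # add-one floor
  expect_gte(res$p_value, 1 / (res$n_perm + 1))
  expect_lte(res$p_value, 1)
})

test_that("seeded tests are reproducible and leave the RNG state alone", {
  set.seed(123)
  a <- rnorm(20)
  b <- rnorm(20)
  state <- .Random.seed
  r1 <- randomization_test(a, b, n_perm = 500, seed = 99, exact_threshold = 0)
  expect_identical(state, .Random.seed)
  r2 <- randomization_test(a, b, n_perm = 500, seed = 99, exact_threshold = 0)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("well-separated groups are always detected", {
  # two groups of 25 separated by 5 spread units
  for (s in 1:20) {
    set.seed(s)
    a <- rnorm(25, 0, 1)
    b <- rnorm(25, 5, 1)
    res <- randomization_test(a, b, n_perm = 2000, seed = s)
    expect_lt(res$p_value, 0.05)
  }
})

test_that("degenerate resampling inputs raise classed errors", {
  expect_error(randomization_test(1, c(1, 2)), class = "thermotol_value_error")
  expect_error(randomization_test(c(1, 2), c(1, 2), n_perm = 0),
               class = "thermotol_config_error")
  expect_error(randomization_test(c(1, NA), c(1, 2)),
               class = "thermotol_value_error")
})

test_that("bootstrap CI of a constant vector is the point itself", {
  res <- bootstrap_median_ci(rep(3.2, 5), n_boot = 200, seed = 1)
  expect_equal(res$lower, 3.2)
  expect_equal(res$upper, 3.2)
  expect_equal(res$median, 3.2)
})

test_that("bootstrap CIs are deterministic under a seed and bracket the median", {
  set.seed(42)
  for (i in 1:10) {
    x <- rgamma(25, shape = 3)
    ci <- bootstrap_median_ci(x, n_boot = 500, seed = i)
    expect_lte(ci$lower, ci$median)
    expect_gte(ci$upper, ci$median)
  }
  x <- rgamma(25, 3)
  expect_identical(tidy(bootstrap_median_ci(x, n_boot = 500, seed = 7)),
                   tidy(bootstrap_median_ci(x, n_boot = 500, seed = 7)))
  expect_error(bootstrap_median_ci(3.0), class = "thermotol_value_error")
  expect_error(bootstrap_median_ci(1:5, level = 1),
               class = "thermotol_config_error")
})
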