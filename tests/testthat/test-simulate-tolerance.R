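test_that("zero spread collapses to the target median exactly", {
  spec <- group_spec("lab25", "female", "cold_ramp", 6.19, spread = 0,
                     skew = 1.5, n = 25)
  out <- simulate_tolerance(spec, seed = 1)
  expect_equal(nrow(out), 25L)
  expect_true(all(out$value == 6.19))
})

test_that("generation is deterministic and CSVs are byte-identical", {
  specs <- default_tolerance_specs()
  a <- simulate_tolerance(specs, seed = 42)
  b <- simulate_tolerance(specs, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$value, simulate_tolerance(specs, seed = 43)$value))

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_tolerance_csv(a, f1)
  write_tolerance_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("sample medians are calibrated to the target medians", {
  # mean-of-sample-medians over 200 seeds stays within 0.15 C of the
  # target for the two cold-ramp female groups
  specs <- dplyr::bind_rows(
    group_spec("lab25", "female", "cold_ramp", 6.19, spread = 1.2, skew = 0.8),
    group_spec("field", "female", "cold_ramp", 0.62, spread = 1.2, skew = 0.8)
  )
  meds <- vapply(1:200, function(s) {
    out <- simulate_tolerance(specs, seed = s)
    c(median(out$value[out$treatment == "lab25"]),
      median(out$value[out$treatment == "field"]))
  }, numeric(2))
  expect_lt(abs(mean(meds[1, ]) - 6.19), 0.15)
  expect_lt(abs(mean(meds[2, ]) - 0.62), 0.15)
})

test_that("skew parameter controls the sampled asymmetry", {
  big <- function(skew) {
    spec <- group_spec("field", "male", "ccr2h", 20, spread = 1,
                       skew = skew, n = 10000)
    simulate_tolerance(spec, seed = 7)$value
  }
  expect_lt(abs(sample_skewness(big(0))), 0.1)
  expect_gt(sample_skewness(big(1.2)), 0.5)
  expect_lt(sample_skewness(big(-1.2)), -0.5)
  # theoretical median is invariant to skew
  expect_lt(abs(median(big(1.2)) - 20), 0.1)
})

test_that("invalid group specifications are rejected by field", {
  expect_error(group_spec("field", "male", "ccr2h", 20, spread = -1),
               class = "thermotol_config_error", regexp = "spread")
  expect_error(group_spec("field", "male", "ccr2h", 20, n = 1),
               class = "thermotol_config_error", regexp = "n")
  expect_error(group_spec("greenhouse", "male", "ccr2h", 20),
               class = "thermotol_config_error", regexp = "treatment")
  expect_error(simulate_tolerance(data.frame()),
               class = "thermotol_config_error")
})
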