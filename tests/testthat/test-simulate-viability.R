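flat_spec <- function(p, rho, vials, eggs = 20L) {
  viability_curve_spec("lab25", constant_prob = p, overdispersion_rho = rho,
                       temperatures = c(20, 25), vials_per_temp = vials,
                       eggs_per_vial = eggs)
}

test_that("a flat curve at p = 1 fills every vial", {
  out <- simulate_viability(flat_spec(1, 0, vials = 10), seed = 1)
  expect_true(all(out$adults_emerged == out$eggs_set))
  empty <- simulate_viability(flat_spec(0, 0.3, vials = 10), seed = 1)
  expect_true(all(empty$adults_emerged == 0L))
})

test_that("rho = 0 reproduces binomial mean and variance", {
  out <- simulate_viability(flat_spec(0.5, 0, vials = 1000), seed = 2)
  props <- out$adults_emerged / out$eggs_set
  expect_gt(mean(props), 0.49)
  expect_lt(mean(props), 0.51)
  ratio <- var(out$adults_emerged) / oracle_bb_var(20, 0.5, 0)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("overdispersion inflates the vial variance by 1 + (m-1)rho", {
  rho <- 0.2
  out <- simulate_viability(flat_spec(0.5, rho, vials = 1000), seed = 3)
  ratio <- var(out$adults_emerged) / oracle_bb_var(20, 0.5, 0)
  target <- 1 + 19 * rho # 4.8
  expect_gt(ratio, target * 0.8)
  expect_lt(ratio, target * 1.2)
  # and the beta-binomial variance formula itself is matched
  expect_lt(abs(var(out$adults_emerged) / oracle_bb_var(20, 0.5, rho) - 1), 0.2)
})

test_that("rho = 0 counts pass a binomial goodness-of-fit check", {
  out <- simulate_viability(flat_spec(0.5, 0, vials = 5000), seed = 4)
  counts <- table(factor(out$adults_emerged, levels = 0:20))
  probs <- dbinom(0:20, 20, 0.5)
  # pool extreme tail cells so expected counts are adequate
  keep <- probs * length(out$adults_emerged) >= 5
  obs <- c(sum(counts[!keep]), counts[keep])
  expe <- c(sum(probs[!keep]), probs[keep])
  gof <- suppressWarnings(chisq.test(obs, p = expe / sum(expe)))
  expect_gt(gof$p.value, 0.01)
})

test_that("the default two-treatment design has the documented shape", {
  out <- simulate_viability(seed = 5)
  expect_equal(nrow(out), 2 * 10 * 20)
  expect_setequal(unique(out$treatment), c("lab25", "field"))
  expect_equal(sort(unique(out$temperature)),
               c(11, 14, 17, 20, 25, 27, 29, 31, 32, 33))
  expect_true(all(out$adults_emerged >= 0 & out$adults_emerged <= out$eggs_set))
  expect_identical(out, simulate_viability(seed = 5))
})

test_that("invalid curve specifications are rejected", {
  expect_error(flat_spec(1.2, 0, vials = 5),
               class = "thermotol_config_error", regexp = "probability")
  expect_error(viability_curve_spec("x", 1:4, temperatures = c(25, 20)),
               class = "thermotol_config_error", regexp = "increasing")
  expect_error(viability_curve_spec("x", 1:4, overdispersion_rho = 1),
               class = "thermotol_config_error", regexp = "rho")
  expect_error(viability_curve_spec("x", coefficients = 1:3),
               class = "thermotol_config_error", regexp = "length 4")
})
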