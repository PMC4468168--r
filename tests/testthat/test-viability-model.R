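test_that("IRLS coefficients match the independent Newton-Raphson oracle", {
  vials <- small_design() # 2 treatments x 5 temps x 4 vials = 40 vials
  fit <- fit_viability_curve(vials, "interaction")
  X <- oracle_design_matrix(vials)
  beta_oracle <- oracle_newton_logit(X, vials$adults_emerged,
                                     vials$eggs_set - vials$adults_emerged)
  expect_equal(unname(fit$coefficients), unname(beta_oracle), tolerance = 1e-6)
})

test_that("a flat no-effect curve yields near-zero curve and treatment terms", {
  specs <- list(
    viability_curve_spec("lab25", constant_prob = 0.7, vials_per_temp = 20),
    viability_curve_spec("field", constant_prob = 0.7, vials_per_temp = 20)
  )
  vials <- simulate_viability(specs, seed = 3)
  fit <- fit_viability_curve(vials, "interaction")
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - qlogis(0.7)), 0.12)
  expect_true(all(abs(fit$coefficients[-1]) < 0.25))
})

test_that("the dispersion estimate tracks the true overdispersion", {
  # binomial data: phi concentrates near 1
  binom <- simulate_viability(default_viability_specs(rho = 0), seed = 8)
  fit0 <- fit_viability_curve(binom, "interaction")
  expect_gt(fit0$dispersion_phi, 0.8)
  expect_lt(fit0$dispersion_phi, 1.2)
  # phi agrees with summary.glm's moment estimator
  expect_equal(fit0$dispersion_phi, summary(fit0$glm)$dispersion,
               tolerance = 1e-6)
  # overdispersed data: phi near 1 + (m-1)rho
  od <- simulate_viability(default_viability_specs(rho = 0.05), seed = 8)
  fit1 <- fit_viability_curve(od, "interaction")
  expect_gt(fit1$dispersion_phi, 1.4)
  expect_lt(fit1$dispersion_phi, 2.6)
})

test_that("quasi correction rescales standard errors but not point estimates", {
  vials <- simulate_viability(seed = 12)
  fit <- fit_viability_curve(vials, "interaction")
  plain <- glm(cbind(adults_emerged, eggs_set - adults_emerged) ~
                 (z + z2 + z3) * treatment,
               family = binomial("logit"),
               data = within(as.data.frame(vials), {
                 tt <- sort(unique(temperature))
                 z <- (temperature - mean(tt)) / sd(tt)
                 z2 <- z^2; z3 <- z^3
                 treatment <- factor(treatment, levels = c("field", "lab25"))
                 rm(tt)
               }),
               control = list(epsilon = 1e-10, maxit = 100))
  expect_equal(unname(fit$coefficients), unname(coef(plain)), tolerance = 1e-12)
  se_quasi <- tidy(fit)$std.error
  se_plain <- summary(plain)$coefficients[, 2]
  expect_equal(unname(se_quasi / se_plain),
               rep(sqrt(fit$dispersion_phi), 8), tolerance = 1e-6)
})

test_that("fitted probabilities recover the generating curve at large egg counts", {
  specs <- default_viability_specs(rho = 0, vials_per_temp = 100L,
                                   eggs_per_vial = 10000L)
  vials <- simulate_viability(specs, seed = 31)
  fit <- fit_viability_curve(vials, "interaction")
  for (tr in c("lab25", "field")) {
    truth <- viability_curve_prob(specs[[tr]])
    est <- predict(fit, specs[[tr]]$temperatures, treatment = tr)
    expect_lt(max(abs(est - truth)), 1e-3)
  }
})

test_that("nested F-tests carry the design degrees of freedom", {
  vials <- simulate_viability(seed = 9)
  full <- fit_viability_curve(vials, "interaction")
  additive <- fit_viability_curve(vials, "additive")
  null <- fit_viability_curve(vials, "intercept")
  ft <- f_test_nested(full, additive)
  expect_equal(ft$df_num, 3L)
  expect_equal(ft$df_den, nrow(vials) - 8L)
  expect_equal(f_test_nested(full, null)$df_num, 7L)
  # degenerate self-comparison
  self <- f_test_nested(full, full)
  expect_equal(self$f_stat, 0)
  expect_equal(self$p_value, 1)
  # cross-check F statistic against anova.glm with the same dispersion
  an <- anova(additive$glm, full$glm, test = "F",
              dispersion = full$dispersion_phi)
  expect_equal(ft$f_stat, an$F[2], tolerance = 1e-10)
  expect_equal(ft$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)
  expect_error(f_test_nested(additive, full), class = "thermotol_value_error")
})

test_that("benign-temperature standardization has its normalization identity", {
  vials <- simulate_viability(seed = 14)
  std <- standardize_viability(vials)
  per_treat <- tapply(std$relative_viability[std$is_benign],
                      std$treatment[std$is_benign], mean)
  expect_equal(as.numeric(per_treat), c(1, 1), tolerance = 1e-12)
  # plain arithmetic: proportion / benign mean
  expect_equal(std$relative_viability,
               std$proportion / std$benign_mean_used)
  # all-equal vials standardize to exactly 1
  flat <- simulate_viability(list(
    viability_curve_spec("lab25", constant_prob = 0.8),
    viability_curve_spec("field", constant_prob = 0.8)
  ), seed = 1)
  flat$adults_emerged <- 16L
  expect_true(all(standardize_viability(flat)$relative_viability == 1))
})

test_that("standardization fails informatively on degenerate input", {
  vials <- simulate_viability(seed = 14)
  expect_error(standardize_viability(vials[vials$temperature != 20, ]),
               class = "thermotol_value_error", regexp = "benign")
  dead <- simulate_viability(list(
    viability_curve_spec("lab25", constant_prob = 0),
    viability_curve_spec("field", constant_prob = 0)
  ), seed = 1)
  expect_error(standardize_viability(dead),
               class = "thermotol_value_error", regexp = "zero")
})

test_that("per-temperature tests cover exactly the non-benign temperatures", {
  vials <- simulate_viability(seed = 17)
  std <- standardize_viability(vials)
  tab <- per_temperature_tests(std, n_perm = 300, seed = 5)
  expect_equal(tab$temperature, c(11, 14, 17, 27, 29, 31, 32, 33))
  expect_equal(nrow(tab), 8L)
  expect_identical(tab, per_temperature_tests(std, n_perm = 300, seed = 5))
  # identical treatment data at a temperature -> p = 1, Md = 0
  mirrored <- std
  mirrored$relative_viability[mirrored$treatment == "field"] <-
    mirrored$relative_viability[mirrored$treatment == "lab25"]
  tab_eq <- per_temperature_tests(mirrored, n_perm = 300, seed = 5)
  expect_true(all(tab_eq$md_diff == 0))
  expect_true(all(tab_eq$p_value == 1))
  # a temperature with a single treatment is skipped with a warning
  drop32 <- std[!(std$temperature == 32 & std$treatment == "field"), ]
  expect_warning(tab_skip <- per_temperature_tests(drop32, n_perm = 300, seed = 5),
                 regexp = "32")
  expect_false(32 %in% tab_skip$temperature)
})
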