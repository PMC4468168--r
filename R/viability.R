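# Thermal-performance-curve analysis of egg-to-adult viability:
# quasi-binomial cubic logistic fits, overdispersion-corrected nested
# F-tests, benign-temperature standardization, and per-temperature
# randomization tests.

# Convert cubic coefficients on z = (T - center)/scale to coefficients
# on raw temperature powers.
poly_rescale <- function(beta, center, scale) {
  out <- numeric(4)
  for (j in 0:3) {
    for (k in j:3) {
      out[j + 1] <- out[j + 1] +
        beta[k + 1] * scale^(-k) * choose(k, j) * (-center)^(k - j)
    }
  }
  names(out) <- c("(Intercept)", "T", "T^2", "T^3")
  out
}

#' Fit a quasi-binomial cubic logistic viability curve
#'
#' Models vial-level counts of emerging adults as grouped binomial
#' observations with a logit link and a cubic polynomial in
#' standardized developmental temperature, optionally crossed with
#' acclimation treatment. The fit is the usual iteratively reweighted
#' least squares binomial fit; overdispersion among vials is then
#' absorbed by the quasi-binomial dispersion estimate
#' phi = Pearson chi-squared / residual df, which scales standard
#' errors by sqrt(phi) but leaves the point estimates untouched.
#'
#' Temperature is centered and scaled (z = (T - mean)/sd over the
#' distinct design temperatures) before powers are taken - raw cubic
#' powers of degrees Celsius are numerically ill-conditioned.
#' Coefficients are reported on both the z scale and the raw
#' temperature scale.
#'
#' @param data Viability records: a data frame with columns
#'   `treatment`, `temperature`, `eggs_set`, `adults_emerged` (and
#'   optionally `vial_id`).
#' @param model `"interaction"` (cubic x treatment, the full model),
#'   `"additive"` (cubic + treatment, interaction omitted) or
#'   `"intercept"` (null model).
#' @return An object of class `"viability_fit"` with elements
#'   `coefficients` (z scale), `coefficients_raw`, `dispersion_phi`,
#'   `deviance`, `pearson_chi2`, `df_resid`, `fitted_probabilities`,
#'   `center`, `scale`, `model`, `n_vials`, and the underlying `glm`
#'   object. [tidy()] returns the quasi-corrected coefficient table;
#'   [glance()] the fit summary.
#' @examples
#' vials <- simulate_viability(seed = 1)
#' fit <- fit_viability_curve(vials)
#' glance(fit)
#' @export
fit_viability_curve <- function(data, model = c("interaction", "additive", "intercept")) {
  model <- match.arg(model)
  validate_viability_records(data)
  n_treat <- length(unique(data$treatment))
  n_temp <- length(unique(data$temperature))
  if (model != "intercept") {
    if (n_treat < 2) value_error("Need at least 2 treatments to fit treatment terms.")
    if (n_temp < 5) value_error("Need at least 5 distinct temperatures for a cubic fit.")
  }

  design_temps <- sort(unique(data$temperature))
  center <- mean(design_temps)
  scale <- sd(design_temps)

  df <- data
  df$z <- (df$temperature - center) / scale
  df$z2 <- df$z^2
  df$z3 <- df$z^3
  treat_levels <- unique(df$treatment)
  treat_levels <- c(intersect("field", treat_levels),
                    setdiff(sort(treat_levels), "field"))
  df$treatment <- factor(df$treatment, levels = treat_levels)

  form <- switch(model,
    interaction = cbind(adults_emerged, eggs_set - adults_emerged) ~
      (z + z2 + z3) * treatment,
    additive = cbind(adults_emerged, eggs_set - adults_emerged) ~
      z + z2 + z3 + treatment,
    intercept = cbind(adults_emerged, eggs_set - adults_emerged) ~ 1
  )
  fit <- glm(form, family = quasibinomial("logit"), data = df,
             control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    fit_error(sprintf("IRLS did not converge in %d iterations (deviance %.6g).",
                      fit$iter, fit$deviance))
  }
  p_hat <- fitted(fit)
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 50) ||
      any(p_hat < 1e-10) || any(p_hat > 1 - 1e-10)) {
    fit_error("Fitted probabilities degenerate to 0/1: separation in the data.")
  }
  df_resid <- df.residual(fit)
  if (df_resid <= 0) value_error("Residual degrees of freedom must be positive.")
  pearson <- sum(residuals(fit, type = "pearson")^2)
  phi <- pearson / df_resid

  beta <- coef(fit)
  raw <- NULL
  if (model == "interaction" || model == "additive") {
    base <- c(beta[["(Intercept)"]], beta[["z"]], beta[["z2"]], beta[["z3"]])
    raw <- list(base = poly_rescale(base, center, scale))
    for (lev in treat_levels[-1]) {
      main <- beta[[paste0("treatment", lev)]]
      if (model == "interaction") {
        inter <- c(main,
                   beta[[paste0("z:treatment", lev)]],
                   beta[[paste0("z2:treatment", lev)]],
                   beta[[paste0("z3:treatment", lev)]])
      } else {
        inter <- c(main, 0, 0, 0)
      }
      raw[[lev]] <- poly_rescale(inter, center, scale)
    }
  }

  structure(list(
    coefficients = beta,
    coefficients_raw = raw,
    dispersion_phi = phi,
    deviance = deviance(fit),
    pearson_chi2 = pearson,
    df_resid = df_resid,
    fitted_probabilities = unname(p_hat),
    center = center, scale = scale,
    model = model,
    n_vials = nrow(df),
    treatment_levels = treat_levels,
    glm = fit
  ), class = "viability_fit")
}

#' @export
print.viability_fit <- function(x, ...) {
  cat(sprintf("Quasi-binomial cubic logistic fit (%s model)\n", x$model))
  cat(sprintf("  %d vials, deviance %.2f on %d df, dispersion phi = %.3f\n",
              x$n_vials, x$deviance, x$df_resid, x$dispersion_phi))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.viability_fit <- function(x, ...) {
  sm <- summary(x$glm, dispersion = x$dispersion_phi)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @exportS3Method generics::glance
glance.viability_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n_vials = x$n_vials,
    n_coefficients = length(x$coefficients),
    deviance = x$deviance, pearson_chi2 = x$pearson_chi2,
    df.residual = x$df_resid, dispersion_phi = x$dispersion_phi
  )
}

#' Predict viability probabilities from a fitted curve
#'
#' @param object A `"viability_fit"`.
#' @param temperature Numeric vector of temperatures (C).
#' @param treatment Treatment label (must be one of the fitted levels);
#'   ignored by the intercept-only model.
#' @param ... Unused.
#' @return Numeric vector of fitted success probabilities.
#' @export
predict.viability_fit <- function(object, temperature, treatment = NULL, ...) {
  z <- (temperature - object$center) / object$scale
  nd <- data.frame(z = z, z2 = z^2, z3 = z^3)
  if (object$model != "intercept") {
    treatment <- treatment %||% object$treatment_levels[1]
    nd$treatment <- factor(rep(treatment, length(z)),
                           levels = object$treatment_levels)
  }
  unname(stats::predict(object$glm, newdata = nd, type = "response"))
}

#' Overdispersion-corrected F-test between nested viability models
#'
#' Compares two fits of the same vials,
#' F = ((dev_reduced - dev_full) / df_num) / phi_full, with df_num the
#' difference in parameter counts and the denominator df the full
#' model's residual df. The dispersion estimate always comes from the
#' full (larger) model.
#'
#' @param full,reduced `"viability_fit"` objects on the same records;
#'   the reduced model's terms must be a subset of the full model's.
#' @return An object of class `"nested_f_test"` with `f_stat`,
#'   `df_num`, `df_den`, `p_value`, `dispersion_phi`. [tidy()] returns
#'   a one-row tibble.
#' @examples
#' vials <- simulate_viability(seed = 1)
#' full <- fit_viability_curve(vials, "interaction")
#' reduced <- fit_viability_curve(vials, "additive")
#' f_test_nested(full, reduced)
#' @export
f_test_nested <- function(full, reduced) {
  stopifnot(inherits(full, "viability_fit"), inherits(reduced, "viability_fit"))
  if (full$n_vials != reduced$n_vials) {
    value_error("Models must be fitted to the same records.")
  }
  full_terms <- names(full$coefficients)
  red_terms <- names(reduced$coefficients)
  if (!all(red_terms %in% full_terms)) {
    value_error("`reduced` must be nested within `full`.")
  }
  df_num <- length(full_terms) - length(red_terms)
  df_den <- full$df_resid
  if (df_num == 0L) {
    # degenerate comparison of a model with itself
    f_stat <- 0
    p <- 1
  } else {
    f_stat <- ((reduced$deviance - full$deviance) / df_num) / full$dispersion_phi
    f_stat <- max(f_stat, 0)
    p <- pf(f_stat, df_num, df_den, lower.tail = FALSE)
  }
  structure(list(f_stat = f_stat, df_num = df_num, df_den = df_den,
                 p_value = p, dispersion_phi = full$dispersion_phi),
            class = "nested_f_test")
}

#' @export
print.nested_f_test <- function(x, ...) {
  cat(sprintf("F_%d,%d = %.3f, p = %.4g (dispersion phi = %.3f)\n",
              x$df_num, x$df_den, x$f_stat, x$p_value, x$dispersion_phi))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nested_f_test <- function(x, ...) {
  tibble::tibble(f_stat = x$f_stat, df_num = x$df_num, df_den = x$df_den,
                 p_value = x$p_value, dispersion_phi = x$dispersion_phi)
}

#' Standardize viability by benign-temperature survival
#'
#' Divides each vial's emergence proportion by its treatment's mean
#' proportion over the benign temperatures (20 and 25 C by default).
#' This removes overall level differences between treatments so that
#' curve *shape* can be compared: within each treatment the
#' standardized values average exactly 1 over the benign vials.
#' Benign-temperature vials are retained in the output and flagged.
#'
#' @param data Viability records (see [fit_viability_curve()]).
#' @param benign_temps Numeric vector of benign temperatures (default
#'   `c(20, 25)`).
#' @return Tibble with columns `vial_id`, `treatment`, `temperature`,
#'   `proportion`, `relative_viability`, `benign_mean_used`,
#'   `is_benign`.
#' @examples
#' standardize_viability(simulate_viability(seed = 1))
#' @export
standardize_viability <- function(data, benign_temps = c(20, 25)) {
  validate_viability_records(data)
  for (tr in unique(data$treatment)) {
    for (bt in benign_temps) {
      if (!any(data$treatment == tr & data$temperature == bt)) {
        value_error(sprintf(
          "Treatment '%s' has no vials at benign temperature %g C.", tr, bt))
      }
    }
  }
  out <- data |>
    dplyr::mutate(proportion = .data$adults_emerged / .data$eggs_set,
                  is_benign = .data$temperature %in% benign_temps) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::mutate(benign_mean_used = mean(.data$proportion[.data$is_benign])) |>
    dplyr::ungroup()
  if (any(out$benign_mean_used == 0)) {
    value_error("Mean benign-temperature survival is zero for a treatment.")
  }
  out |>
    dplyr::mutate(relative_viability = .data$proportion / .data$benign_mean_used) |>
    dplyr::select(dplyr::any_of("vial_id"), "treatment", "temperature",
                  "proportion", "relative_viability", "benign_mean_used",
                  "is_benign")
}

#' Per-temperature randomization tests on standardized viability
#'
#' At every non-benign temperature, compares vial-level relative
#' viabilities between the two treatments with a
#' [randomization_test()] on the difference of medians. Temperatures at
#' which only one treatment has vials are skipped with a warning.
#' P-values are reported without multiple-testing adjustment by
#' default, mirroring how such per-temperature tables are usually
#' published; set `holm = TRUE` to add a Holm-adjusted column.
#'
#' @param standardized Output of [standardize_viability()].
#' @param n_perm Permutations per test (default 100,000).
#' @param seed Optional integer master seed; each temperature gets its
#'   own derived seed so results do not depend on evaluation order.
#' @param reference Treatment used as the subtrahend of the Md
#'   statistic (default `"field"`, so Md = Md_other - Md_field).
#' @param holm Add Holm-adjusted p-values? Default `FALSE`.
#' @return Tibble ordered by temperature with columns `temperature`,
#'   `md_diff`, `p_value`, `n_a`, `n_b`, `exact` (and `p_holm` if
#'   requested).
#' @examples
#' std <- standardize_viability(simulate_viability(seed = 1))
#' per_temperature_tests(std, n_perm = 999, seed = 1)
#' @export
per_temperature_tests <- function(standardized, n_perm = 100000L, seed = NULL,
                                  reference = "field", holm = FALSE) {
  needed <- c("treatment", "temperature", "relative_viability", "is_benign")
  if (!all(needed %in% names(standardized))) {
    value_error("`standardized` must come from standardize_viability().")
  }
  treats <- unique(standardized$treatment)
  if (length(treats) != 2L) {
    value_error("Per-temperature tests need exactly 2 treatments.")
  }
  if (!reference %in% treats) reference <- treats[2]
  other <- setdiff(treats, reference)
  temps <- sort(unique(standardized$temperature[!standardized$is_benign]))
  rows <- purrr::map(temps, function(tmp) {
    sub <- standardized[standardized$temperature == tmp, ]
    a <- sub$relative_viability[sub$treatment == other]
    b <- sub$relative_viability[sub$treatment == reference]
    if (length(a) < 2L || length(b) < 2L) {
      warn(sprintf("Temperature %g C lacks both treatments; skipped.", tmp))
      return(NULL)
    }
    stage_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("per_temp/", tmp))
    res <- randomization_test(a, b, n_perm = n_perm, seed = stage_seed)
    tibble::tibble(temperature = tmp, md_diff = res$md_diff,
                   p_value = res$p_value, n_a = res$n_a, n_b = res$n_b,
                   exact = res$exact)
  })
  out <- purrr::list_rbind(rows)
  if (holm && nrow(out)) out$p_holm <- stats::p.adjust(out$p_value, "holm")
  out
}
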