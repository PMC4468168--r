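# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the package's own code paths.

# Brute-force two-tailed permutation p-value on the difference of
# medians, enumerating every assignment of the pooled values to the
# first group (positions, not sorted values).
oracle_perm_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  obs <- abs(stats::median(a) - stats::median(b))
  splits <- utils::combn(n, na)
  stats <- apply(splits, 2, function(idx) {
    abs(stats::median(pool[idx]) - stats::median(pool[-idx]))
  })
  mean(stats >= obs)
}

# Newton-Raphson maximizer of the grouped binomial log-likelihood with
# logit link, written against the design matrix directly (no glm, no
# IRLS wrapper). Returns the coefficient vector.
oracle_newton_logit <- function(X, successes, failures, tol = 1e-12,
                                max_iter = 200) {
  beta <- rep(0, ncol(X))
  m <- successes + failures
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (successes - m * p))
    W <- m * p * (1 - p)
    hess <- t(X) %*% (X * W)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Design matrix matching the package's interaction parameterization
# (field as reference level), for cross-checking fits.
oracle_design_matrix <- function(data) {
  temps <- sort(unique(data$temperature))
  z <- (data$temperature - mean(temps)) / stats::sd(temps)
  treat_levels <- c(intersect("field", unique(data$treatment)),
                    setdiff(sort(unique(data$treatment)), "field"))
  tr <- as.numeric(data$treatment == treat_levels[2])
  cbind(1, z, z^2, z^3, tr, z * tr, z^2 * tr, z^3 * tr)
}

# Theoretical variance of a beta-binomial count: m*p*(1-p)*(1+(m-1)*rho).
oracle_bb_var <- function(m, p, rho) {
  m * p * (1 - p) * (1 + (m - 1) * rho)
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}

# Shared 40-vial two-treatment fixture design.
small_design <- function(seed = 21, vials = 4L) {
  specs <- list(
    viability_curve_spec("lab25", c(1.5, -0.4, -1.0, -0.2),
                         overdispersion_rho = 0.05,
                         temperatures = c(11, 17, 25, 29, 33),
                         vials_per_temp = vials, eggs_per_vial = 20),
    viability_curve_spec("field", c(0.9, -0.9, -1.4, -0.4),
                         overdispersion_rho = 0.05,
                         temperatures = c(11, 17, 25, 29, 33),
                         vials_per_temp = vials, eggs_per_vial = 20)
  )
  simulate_viability(specs, seed = seed)
}

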