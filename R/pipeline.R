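# Orchestration: simulate -> analyze -> report, plus the microclimate
# summary and the arithmetic-consistency checks on the published
# reference medians.

#' Analysis configuration
#'
#' Bundles the resampling budgets, benign temperatures, generator
#' specifications and the master seed. Every stochastic stage derives
#' its own seed from the master seed and a stage label
#' ([derive_seed()]), so a configuration fully determines the output.
#'
#' @param seed Integer master seed (default 1).
#' @param n_perm Permutations per randomization test (default 100,000).
#' @param n_boot Bootstrap resamples per CI (default 10,000).
#' @param ci_level Confidence level for bootstrap CIs (default 0.95).
#' @param benign_temps Benign developmental temperatures used for
#'   standardization (default `c(20, 25)`).
#' @param tolerance_specs Group specs for [simulate_tolerance()].
#' @param viability_specs Curve specs for [simulate_viability()].
#' @param templog_spec Spec for [simulate_temperature_log()].
#' @param fast Use reduced budgets (n_perm 5,000, n_boot 1,000),
#'   handy for smoke runs. Default `FALSE`.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(seed = 1L, n_perm = 100000L, n_boot = 10000L,
                            ci_level = 0.95, benign_temps = c(20, 25),
                            tolerance_specs = default_tolerance_specs(),
                            viability_specs = default_viability_specs(),
                            templog_spec = temperature_log_spec(),
                            fast = FALSE) {
  if (n_perm < 1 || n_boot < 1) config_error("`n_perm` and `n_boot` must be >= 1.")
  if (fast) {
    n_perm <- min(n_perm, 5000L)
    n_boot <- min(n_boot, 1000L)
  }
  structure(list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 benign_temps = benign_temps,
                 tolerance_specs = tolerance_specs,
                 viability_specs = viability_specs,
                 templog_spec = templog_spec),
            class = "analysis_config")
}

# All pairwise comparisons the tolerance analysis performs for one
# assay, given the treatments present in it.
tolerance_comparison_plan <- function(treatments, sexes) {
  plan <- list()
  for (sx in sexes) {
    if (all(c("lab25", "field") %in% treatments)) {
      plan <- c(plan, list(list(type = "treatment_within_sex", stratum = sx,
                                a = "lab25", b = "field")))
    }
    if ("lab13" %in% treatments) {
      for (other in intersect(c("field", "lab25"), treatments)) {
        plan <- c(plan, list(list(type = "treatment_within_sex", stratum = sx,
                                  a = "lab13", b = other)))
      }
    }
  }
  for (tr in treatments) {
    plan <- c(plan, list(list(type = "sex_within_treatment", stratum = tr,
                              a = "male", b = "female")))
  }
  plan
}

#' Run the tolerance-assay analysis
#'
#' For each assay, runs difference-in-medians randomization tests for
#' (i) laboratory-25C vs field flies within each sex, (ii) males vs
#' females within each treatment, and (iii) where 13C-reared laboratory
#' flies are present (the ramping assays in the shipped design),
#' lab-13C vs field and lab-13C vs lab-25C within each sex. Every group
#' median is accompanied by a percentile bootstrap confidence interval.
#' Groups missing from the data are reported as untestable rows and the
#' run continues.
#'
#' @param config An [analysis_config()].
#' @param data Optional tolerance records; when `NULL`, data are
#'   simulated from `config$tolerance_specs` under a derived seed.
#' @return An object of class `"tolerance_report"`: a list with
#'   `tests` (one row per comparison: assay, type, stratum, groups,
#'   medians, Md difference, p-value) and `medians` (one row per group
#'   with bootstrap CI).
#' @examples
#' cfg <- analysis_config(seed = 1, fast = TRUE)
#' rep <- run_tolerance_analysis(cfg)
#' head(rep$tests)
#' @export
run_tolerance_analysis <- function(config = analysis_config(), data = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(data)) {
    data <- simulate_tolerance(config$tolerance_specs,
                               seed = derive_seed(config$seed, "tolerance_data"))
  }

  groups <- data |>
    dplyr::group_by(.data$assay, .data$treatment, .data$sex) |>
    dplyr::summarise(values = list(.data$value), n = dplyr::n(),
                     .groups = "drop")
  get_values <- function(assay, treatment, sex) {
    row <- groups[groups$assay == assay & groups$treatment == treatment &
                    groups$sex == sex, ]
    if (nrow(row) == 0L) NULL else row$values[[1]]
  }

  medians <- groups |>
    dplyr::mutate(purrr::pmap_dfr(
      list(.data$assay, .data$treatment, .data$sex, .data$values),
      function(assay, treatment, sex, v) {
        ci <- bootstrap_median_ci(
          v, n_boot = config$n_boot, level = config$ci_level,
          seed = derive_seed(config$seed,
                             paste("boot", assay, treatment, sex, sep = "/")))
        tibble::tibble(median = ci$median, ci_lower = ci$lower,
                       ci_upper = ci$upper)
      })) |>
    dplyr::select(-"values")

  tests <- purrr::map(unique(data$assay), function(assay) {
    present <- groups[groups$assay == assay, ]
    plan <- tolerance_comparison_plan(unique(present$treatment),
                                      unique(present$sex))
    purrr::map(plan, function(cmp) {
      if (cmp$type == "treatment_within_sex") {
        va <- get_values(assay, cmp$a, cmp$stratum)
        vb <- get_values(assay, cmp$b, cmp$stratum)
      } else {
        va <- get_values(assay, cmp$stratum, cmp$a)
        vb <- get_values(assay, cmp$stratum, cmp$b)
      }
      base <- tibble::tibble(assay = assay, comparison = cmp$type,
                             stratum = cmp$stratum,
                             group_a = cmp$a, group_b = cmp$b)
      if (is.null(va) || is.null(vb)) {
        return(dplyr::mutate(base, md_a = NA_real_, md_b = NA_real_,
                             md_diff = NA_real_, p_value = NA_real_,
                             n_a = length(va %||% numeric()),
                             n_b = length(vb %||% numeric()),
                             exact = NA, note = "untestable: group missing"))
      }
      res <- randomization_test(
        va, vb, n_perm = config$n_perm,
        seed = derive_seed(config$seed,
                           paste("perm", assay, cmp$type, cmp$stratum,
                                 cmp$a, cmp$b, sep = "/")))
      dplyr::mutate(base, md_a = res$md_a, md_b = res$md_b,
                    md_diff = res$md_diff, p_value = res$p_value,
                    n_a = res$n_a, n_b = res$n_b, exact = res$exact,
                    note = NA_character_)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  structure(list(tests = tests, medians = medians,
                 seed = config$seed, n_perm = config$n_perm,
                 n_boot = config$n_boot, ci_level = config$ci_level),
            class = "tolerance_report")
}

#' @export
print.tolerance_report <- function(x, ...) {
  cat(sprintf("Tolerance analysis (seed %d, %d permutations, %d bootstrap resamples)\n",
              x$seed, x$n_perm, x$n_boot))
  print(x$tests, n = nrow(x$tests))
  invisible(x)
}

#' Run the egg-to-adult viability analysis
#'
#' Fits the full (cubic x treatment), additive (interaction omitted)
#' and intercept-only quasi-binomial models, runs the
#' overdispersion-corrected F-tests (full vs null, then interaction),
#' standardizes survival by mean benign-temperature survival within
#' treatment, and runs per-temperature randomization tests at all
#' non-benign temperatures. Also exports a fitted-curve grid (raw and
#' standardized) for plotting.
#'
#' @inheritParams run_tolerance_analysis
#' @param data Optional viability records; when `NULL`, simulated from
#'   `config$viability_specs` under a derived seed.
#' @return An object of class `"viability_report"`: a list with
#'   `fits`, `model_tests` (F, df, p, phi), `per_temperature` (Md and
#'   p per temperature), `standardized`, `curve` (temperature grid with
#'   fitted and standardized fitted values), `dispersion_phi`.
#' @examples
#' cfg <- analysis_config(seed = 1, fast = TRUE)
#' rep <- run_viability_analysis(cfg)
#' rep$model_tests
#' @export
run_viability_analysis <- function(config = analysis_config(), data = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(data)) {
    data <- simulate_viability(config$viability_specs,
                               seed = derive_seed(config$seed, "viability_data"))
  }
  fits <- list(
    interaction = fit_viability_curve(data, "interaction"),
    additive = fit_viability_curve(data, "additive"),
    intercept = fit_viability_curve(data, "intercept")
  )
  ft_null <- f_test_nested(fits$interaction, fits$intercept)
  ft_int <- f_test_nested(fits$interaction, fits$additive)
  model_tests <- dplyr::bind_rows(
    dplyr::mutate(tidy(ft_null), comparison = "full_vs_null", .before = 1),
    dplyr::mutate(tidy(ft_int), comparison = "interaction", .before = 1)
  )

  standardized <- standardize_viability(data, config$benign_temps)
  per_temp <- per_temperature_tests(standardized, n_perm = config$n_perm,
                                    seed = derive_seed(config$seed, "per_temp_tests"))

  benign_means <- standardized |>
    dplyr::distinct(.data$treatment, .data$benign_mean_used)
  grid <- seq(min(data$temperature), max(data$temperature), by = 0.25)
  curve <- purrr::map(unique(data$treatment), function(tr) {
    p <- predict(fits$interaction, grid, treatment = tr)
    bm <- benign_means$benign_mean_used[benign_means$treatment == tr]
    tibble::tibble(treatment = tr, temperature = grid,
                   fitted_probability = p,
                   standardized_fitted = p / bm)
  }) |> purrr::list_rbind()

  structure(list(fits = fits, model_tests = model_tests,
                 per_temperature = per_temp, standardized = standardized,
                 curve = curve,
                 dispersion_phi = fits$interaction$dispersion_phi,
                 seed = config$seed, n_perm = config$n_perm),
            class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  cat(sprintf("Viability analysis (seed %d, %d permutations)\n", x$seed, x$n_perm))
  cat(sprintf("  dispersion phi = %.3f\n", x$dispersion_phi))
  cat("Model comparisons:\n"); print(x$model_tests)
  cat("Per-temperature tests (benign temperatures omitted):\n")
  print(x$per_temperature, n = nrow(x$per_temperature))
  invisible(x)
}

#' Summarize a microhabitat temperature log
#'
#' Per-sensor means, mean daily amplitudes (max - min within each
#' day), and each sensor's offset from air temperature, computed over
#' whole days only (days with a complete complement of readings for
#' the sensor).
#'
#' @param log Tibble with columns `timestamp`, `sensor`, `temp_c`.
#' @return Tibble with one row per sensor: `sensor`, `n_days`,
#'   `mean_c`, `daily_amplitude_c`, `offset_vs_air_c` (NA for air).
#' @examples
#' log <- simulate_temperature_log(seed = 1)
#' summarize_microclimate(log)
#' @export
summarize_microclimate <- function(log) {
  needed <- c("timestamp", "sensor", "temp_c")
  if (!all(needed %in% names(log))) {
    value_error("`log` must have columns timestamp, sensor, temp_c.")
  }
  intervals <- diff(sort(unique(log$timestamp)))
  units(intervals) <- "mins"
  step <- min(as.numeric(intervals))
  per_day <- (24 * 60) / step

  daily <- log |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$sensor, .data$date) |>
    dplyr::summarise(n = dplyr::n(), mean_c = mean(.data$temp_c),
                     amp = max(.data$temp_c) - min(.data$temp_c),
                     .groups = "drop") |>
    dplyr::filter(.data$n == per_day)
  if (nrow(daily) == 0L) {
    value_error("Need at least one whole day of records per sensor.")
  }
  smry <- daily |>
    dplyr::group_by(.data$sensor) |>
    dplyr::summarise(n_days = dplyr::n(), mean_c = mean(.data$mean_c),
                     daily_amplitude_c = mean(.data$amp), .groups = "drop")
  if (!"air" %in% smry$sensor) {
    value_error("`log` must contain an 'air' sensor for offsets.")
  }
  air_mean <- smry$mean_c[smry$sensor == "air"]
  smry |>
    dplyr::mutate(offset_vs_air_c = ifelse(.data$sensor == "air", NA_real_,
                                           .data$mean_c - air_mean))
}

# ---- published reference medians and their arithmetic identities ---------

#' Published reference medians for the default configuration
#'
#' The group medians (ramping assays, C) that the shipped generator
#' defaults reproduce: winter-acclimatized field flies, laboratory
#' flies reared at 25 C, and laboratory flies reared at 13 C, by sex.
#'
#' @return Tibble with columns `assay`, `treatment`, `sex`, `median`.
#' @export
reference_medians <- function() {
  tibble::tribble(
    ~assay,      ~treatment, ~sex,     ~median,
    "cold_ramp", "field",    "female",  0.62,
    "cold_ramp", "field",    "male",    0.74,
    "cold_ramp", "lab25",    "female",  6.19,
    "cold_ramp", "lab25",    "male",    5.92,
    "heat_ramp", "lab25_minus_field", "female", 1.67,
    "heat_ramp", "lab25_minus_field", "male",   2.57,
    "heat_ramp", "lab13_minus_field", "female", 0.32,
    "heat_ramp", "lab13_minus_field", "male",   0.26,
    "cold_ramp", "lab13_minus_field", "female", 0.03,
    "cold_ramp", "lab13_minus_field", "male",   0.25
  )
}

#' Verify arithmetic identities among the reference medians
#'
#' The published ramping-assay medians and median differences are
#' inter-related: e.g. the female cold-ramp difference must equal
#' 6.19 - 0.62 = 5.57, and the 13C-laboratory comparisons must be
#' consistent with the chained differences
#' (Md_lab13-lab25 = Md_lab13-field + Md_field - Md_lab25 for the cold
#' ramp, and Md_lab13-lab25 = Md_lab13-field - Md_lab25-field for the
#' heat ramp). This function recomputes each identity from the
#' component values and checks it against the published combined value.
#'
#' @param tol Absolute tolerance (default 1e-9).
#' @return Tibble with columns `identity`, `expected`, `computed`,
#'   `pass`.
#' @examples
#' verify_reference_identities()
#' @export
verify_reference_identities <- function(tol = 1e-9) {
  ref <- reference_medians()
  val <- function(assay, treatment, sex) {
    ref$median[ref$assay == assay & ref$treatment == treatment & ref$sex == sex]
  }
  rows <- tibble::tribble(
    ~identity, ~expected, ~computed,
    "cold_ramp female Md_lab25-field", 5.57,
      val("cold_ramp", "lab25", "female") - val("cold_ramp", "field", "female"),
    "cold_ramp male Md_lab25-field", 5.18,
      val("cold_ramp", "lab25", "male") - val("cold_ramp", "field", "male"),
    "cold_ramp field Md_males-females", 0.12,
      val("cold_ramp", "field", "male") - val("cold_ramp", "field", "female"),
    "cold_ramp female Md_lab13-lab25", -5.54,
      val("cold_ramp", "lab13_minus_field", "female") +
        val("cold_ramp", "field", "female") - val("cold_ramp", "lab25", "female"),
    "cold_ramp male Md_lab13-lab25", -4.93,
      val("cold_ramp", "lab13_minus_field", "male") +
        val("cold_ramp", "field", "male") - val("cold_ramp", "lab25", "male"),
    "heat_ramp female Md_lab13-lab25", -1.35,
      val("heat_ramp", "lab13_minus_field", "female") -
        val("heat_ramp", "lab25_minus_field", "female"),
    "heat_ramp male Md_lab13-lab25", -2.31,
      val("heat_ramp", "lab13_minus_field", "male") -
        val("heat_ramp", "lab25_minus_field", "male")
  )
  dplyr::mutate(rows, pass = abs(.data$expected - .data$computed) <= tol)
}
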