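# Specification objects for the synthetic-data generators, plus the
# shipped default configurations calibrated to the published group
# medians and viability pattern.

ASSAYS <- c("heat_knockdown", "heat_ramp", "ccr2h", "cold_ramp")
TREATMENTS <- c("field", "lab25", "lab13")
SEXES <- c("male", "female")

#' Unit of measurement for a tolerance assay
#'
#' Knockdown and chill-coma recovery assays are scored as times in
#' minutes; ramping assays are scored as critical temperatures in
#' degrees Celsius.
#'
#' @param assay Character vector of assay names.
#' @return Character vector, `"min"` or `"degC"`.
#' @export
assay_unit <- function(assay) {
  ifelse(assay %in% c("heat_knockdown", "ccr2h"), "min", "degC")
}

#' Group specification for the tolerance-score generator
#'
#' One row per experimental group (treatment x sex x assay). Scores are
#' drawn from a location-shifted gamma family whose theoretical median
#' equals `target_median` exactly; `spread` is the standard deviation of
#' the underlying distribution and `skew` its skewness (0 gives a
#' normal; the sign of `skew` flips the heavy tail).
#'
#' @param treatment One of `"field"`, `"lab25"`, `"lab13"`.
#' @param sex `"male"` or `"female"`.
#' @param assay One of `"heat_knockdown"`, `"heat_ramp"`, `"ccr2h"`,
#'   `"cold_ramp"`.
#' @param target_median Target median (minutes for knockdown/recovery
#'   assays, degrees Celsius for ramping assays).
#' @param spread Non-negative spread (same units); 0 gives the
#'   degenerate constant distribution.
#' @param skew Dimensionless skewness; 0 = symmetric.
#' @param n Number of flies (default 25; typical assays use 22-25).
#' @return A one-row tibble; bind rows to build a full design.
#' @examples
#' group_spec("field", "female", "cold_ramp", 0.62, spread = 1.2, skew = 0.8)
#' @export
group_spec <- function(treatment, sex, assay, target_median,
                       spread = 1, skew = 0, n = 25L) {
  spec <- tibble::tibble(
    treatment = as.character(treatment), sex = as.character(sex),
    assay = as.character(assay),
    target_median = as.numeric(target_median),
    spread = as.numeric(spread), skew = as.numeric(skew),
    n = as.integer(n)
  )
  validate_group_specs(spec)
  spec
}

validate_group_specs <- function(specs) {
  if (!is.data.frame(specs) || nrow(specs) == 0L) {
    config_error("`specs` must be a non-empty data frame of group specifications.")
  }
  needed <- c("treatment", "sex", "assay", "target_median", "spread", "skew", "n")
  missing_cols <- setdiff(needed, names(specs))
  if (length(missing_cols)) {
    config_error(paste0("`specs` is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!all(specs$treatment %in% TREATMENTS)) {
    config_error("`treatment` must be one of: field, lab25, lab13.")
  }
  if (!all(specs$sex %in% SEXES)) {
    config_error("`sex` must be 'male' or 'female'.")
  }
  if (!all(specs$assay %in% ASSAYS)) {
    config_error(paste0("`assay` must be one of: ",
                        paste(ASSAYS, collapse = ", "), "."))
  }
  if (any(!is.finite(specs$target_median))) {
    config_error("`target_median` must be finite.")
  }
  if (any(!is.finite(specs$spread) | specs$spread < 0)) {
    config_error("`spread` must be non-negative.")
  }
  if (any(is.na(specs$n) | specs$n < 2)) {
    config_error("`n` must be at least 2.")
  }
  invisible(specs)
}

#' Default tolerance-assay design
#'
#' The shipped generator configuration: 25 males and 25 females per
#' treatment in each of the four assays (field and lab-25C flies in all
#' four; lab-13C flies in the two ramping assays). Group medians
#' reproduce the published winter-acclimatization effect sizes, e.g. a
#' female CTmin of 0.62 C in field flies against 6.19 C in 25 C
#' laboratory flies. Absolute time levels for the knockdown and
#' chill-coma assays are not published and were fixed once at
#' field-realistic values; spreads and skews are free parameters of the
#' generator chosen to mimic the skewed, heteroscedastic score
#' distributions these assays produce (see the package vignette).
#'
#' @param n Flies per group (default 25).
#' @return Tibble of group specifications, one row per group.
#' @export
default_tolerance_specs <- function(n = 25L) {
  med <- tibble::tribble(
    ~assay,           ~treatment, ~male,  ~female,
    "heat_knockdown", "field",     32.15,  40.00,
    "heat_knockdown", "lab25",    119.22, 151.13,
    "heat_ramp",      "field",     36.21,  37.00,
    "heat_ramp",      "lab25",     38.78,  38.67,
    "heat_ramp",      "lab13",     36.47,  37.32,
    "ccr2h",          "field",     28.15,  25.00,
    "ccr2h",          "lab25",     26.03,  26.70,
    "cold_ramp",      "field",      0.74,   0.62,
    "cold_ramp",      "lab25",      5.92,   6.19,
    "cold_ramp",      "lab13",      0.99,   0.65
  )
  shape <- tibble::tribble(
    ~assay,           ~spread, ~skew,
    "heat_knockdown",  15.0,    1.0,
    "heat_ramp",        0.6,   -0.8,
    "ccr2h",           18.0,    1.2,
    "cold_ramp",        1.2,    0.8
  )
  med |>
    tidyr::pivot_longer(c("male", "female"), names_to = "sex",
                        values_to = "target_median") |>
    dplyr::left_join(shape, by = "assay") |>
    dplyr::mutate(n = as.integer(n)) |>
    dplyr::select("treatment", "sex", "assay", "target_median",
                  "spread", "skew", "n")
}

#' Viability-curve specification for the vial-count generator
#'
#' Describes one treatment's egg-to-adult viability curve: a cubic
#' polynomial on the logit scale in standardized temperature
#' z = (T - mean(T)) / sd(T) (mean and sd over the design temperatures),
#' sampled as beta-binomial vial counts with intra-vial correlation
#' `overdispersion_rho` (rho = 0 reduces exactly to binomial sampling;
#' the variance of a vial count is inflated by 1 + (eggs - 1) * rho).
#'
#' @param treatment `"field"` or `"lab25"` (or any label).
#' @param coefficients Numeric length-4 vector (intercept, z, z^2, z^3)
#'   on the logit scale. Ignored when `constant_prob` is given.
#' @param overdispersion_rho Intra-vial correlation in `[0, 1)`.
#' @param temperatures Strictly increasing developmental temperatures
#'   (C); default the ten-temperature design 11-33 C.
#' @param vials_per_temp Vials per temperature (default 20).
#' @param eggs_per_vial Eggs per vial (default 20).
#' @param constant_prob Optional flat success probability in `[0, 1]`,
#'   overriding the curve (useful for degenerate checks).
#' @return A list of class `"viability_curve_spec"`.
#' @examples
#' viability_curve_spec("lab25", c(2.3, -0.7, -1.9, -0.3))
#' @export
viability_curve_spec <- function(treatment, coefficients = NULL,
                                 overdispersion_rho = 0,
                                 temperatures = c(11, 14, 17, 20, 25, 27, 29, 31, 32, 33),
                                 vials_per_temp = 20L,
                                 eggs_per_vial = 20L,
                                 constant_prob = NULL) {
  if (is.unsorted(temperatures, strictly = TRUE)) {
    config_error("`temperatures` must be strictly increasing.")
  }
  if (length(temperatures) < 2L) {
    config_error("`temperatures` needs at least 2 values.")
  }
  if (!is.numeric(overdispersion_rho) || length(overdispersion_rho) != 1L ||
      overdispersion_rho < 0 || overdispersion_rho >= 1) {
    config_error("`overdispersion_rho` must lie in [0, 1).")
  }
  if (vials_per_temp < 1L) config_error("`vials_per_temp` must be >= 1.")
  if (eggs_per_vial < 1L) config_error("`eggs_per_vial` must be >= 1.")
  if (is.null(constant_prob)) {
    if (!is.numeric(coefficients) || length(coefficients) != 4L ||
        any(!is.finite(coefficients))) {
      config_error("`coefficients` must be a finite numeric vector of length 4.")
    }
  } else {
    if (!is.numeric(constant_prob) || length(constant_prob) != 1L ||
        is.na(constant_prob) || constant_prob < 0 || constant_prob > 1) {
      config_error("`constant_prob` (curve probability) must lie in [0, 1].")
    }
  }
  structure(list(treatment = as.character(treatment),
                 coefficients = coefficients,
                 overdispersion_rho = overdispersion_rho,
                 temperatures = as.numeric(temperatures),
                 vials_per_temp = as.integer(vials_per_temp),
                 eggs_per_vial = as.integer(eggs_per_vial),
                 constant_prob = constant_prob),
            class = "viability_curve_spec")
}

#' Curve probabilities implied by a viability specification
#'
#' @param spec A [viability_curve_spec()].
#' @param temperatures Temperatures at which to evaluate (defaults to
#'   the spec's design temperatures).
#' @return Numeric vector of success probabilities.
#' @export
viability_curve_prob <- function(spec, temperatures = spec$temperatures) {
  stopifnot(inherits(spec, "viability_curve_spec"))
  if (!is.null(spec$constant_prob)) {
    return(rep(spec$constant_prob, length(temperatures)))
  }
  z <- (temperatures - mean(spec$temperatures)) / sd(spec$temperatures)
  plogis(cbind(1, z, z^2, z^3) %*% spec$coefficients)[, 1]
}

#' Default egg-to-adult viability design
#'
#' The shipped two-treatment generator configuration: 20 vials of 20
#' eggs at each of ten developmental temperatures (11-33 C) per
#' treatment, beta-binomial counts with rho = 0.05 (dispersion factor
#' about 1.95 at 20 eggs, matching the clear overdispersion such vial
#' designs show). The laboratory (25 C) curve is a realistic unimodal
#' viability profile peaking near 20-25 C; the field curve was
#' calibrated so that, after benign-temperature standardization,
#' viability matches the laboratory curve at 11-17 C but is strongly
#' depressed at 27-31 C - the cross-generational cost-of-winter
#' signature the analysis is designed to detect. Cubic geometry forces
#' the field deficit to persist at 32-33 C (two cubics agreeing at four
#' points are identical); the vignette discusses this limitation.
#'
#' @param rho Intra-vial correlation (default 0.05).
#' @param vials_per_temp,eggs_per_vial Design size (defaults 20 and 20).
#' @return Named list of two [viability_curve_spec()] objects
#'   (`lab25`, `field`).
#' @export
default_viability_specs <- function(rho = 0.05, vials_per_temp = 20L,
                                    eggs_per_vial = 20L) {
  list(
    lab25 = viability_curve_spec(
      "lab25", coefficients = c(2.32692, -0.65776, -1.85968, -0.31211),
      overdispersion_rho = rho, vials_per_temp = vials_per_temp,
      eggs_per_vial = eggs_per_vial),
    field = viability_curve_spec(
      "field", coefficients = c(1.59527, -1.72485, -3.00963, -0.75038),
      overdispersion_rho = rho, vials_per_temp = vials_per_temp,
      eggs_per_vial = eggs_per_vial)
  )
}

#' Temperature-logger specification
#'
#' Describes synthetic half-hourly microhabitat temperature traces for
#' three sensors: ambient air plus two depths inside a compost heap.
#' Fermentation holds the heap about `heap_offset` degrees above air
#' temperature and buffers the daily cycle: each heap sensor's daily
#' amplitude is the air amplitude multiplied by its damping factor.
#' Readings are quantized to 0.1 C after noise, mimicking logger
#' resolution.
#'
#' @param start,end POSIXct timestamps (UTC recommended); `end` must be
#'   after `start`.
#' @param interval_minutes Logging interval; must divide a day evenly
#'   (default 30).
#' @param air_mean Mean air temperature, C (default 2, early winter).
#' @param air_daily_amplitude Half peak-to-trough daily air swing, C
#'   (default 4).
#' @param heap_offset Heap-minus-air offset, C (default 8).
#' @param amplitude_damping Named numeric vector of damping factors in
#'   `[0, 1]` for the heap sensors (default top 0.35, bottom 0.10).
#' @param noise_sd Gaussian sensor/weather noise sd, C (default 0.3).
#' @return A list of class `"temperature_log_spec"`.
#' @export
temperature_log_spec <- function(start = as.POSIXct("2013-12-01 00:00:00", tz = "UTC"),
                                 end = as.POSIXct("2013-12-15 00:00:00", tz = "UTC"),
                                 interval_minutes = 30L,
                                 air_mean = 2, air_daily_amplitude = 4,
                                 heap_offset = 8,
                                 amplitude_damping = c(heap_top = 0.35, heap_bottom = 0.10),
                                 noise_sd = 0.3) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!(end > start)) config_error("`end` must be after `start`.")
  if ((24 * 60) %% interval_minutes != 0) {
    config_error("`interval_minutes` must divide a day evenly.")
  }
  if (any(amplitude_damping < 0 | amplitude_damping > 1)) {
    config_error("`amplitude_damping` must lie in [0, 1].")
  }
  if (is.null(names(amplitude_damping)) || any(names(amplitude_damping) == "")) {
    config_error("`amplitude_damping` must be a named vector (one entry per heap sensor).")
  }
  if (noise_sd < 0) config_error("`noise_sd` must be non-negative.")
  structure(list(start = start, end = end,
                 interval_minutes = as.integer(interval_minutes),
                 air_mean = air_mean,
                 air_daily_amplitude = air_daily_amplitude,
                 heap_offset = heap_offset,
                 amplitude_damping = amplitude_damping,
                 noise_sd = noise_sd),
            class = "temperature_log_spec")
}
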