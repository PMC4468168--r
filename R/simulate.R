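# Synthetic-data generators emulating the assay designs: per-fly
# tolerance scores, per-vial viability counts, and microhabitat
# temperature logs.

# Draw n values from the location-shifted (optionally sign-flipped)
# gamma family with theoretical median `target`, sd `spread`, skewness
# `skew`. spread = 0 degenerates to a constant; skew = 0 to a normal.
draw_skewed <- function(n, target, spread, skew) {
  if (spread == 0) {
    return(rep(target, n))
  }
  if (skew == 0) {
    return(rnorm(n, mean = target, sd = spread))
  }
  shape <- (2 / abs(skew))^2
  scale <- spread / sqrt(shape)
  g <- rgamma(n, shape = shape, scale = scale)
  med_g <- qgamma(0.5, shape = shape, scale = scale)
  target + sign(skew) * (g - med_g)
}

#' Simulate per-fly tolerance scores
#'
#' Draws one record per fly from each group specification. Scores come
#' from a location-shifted gamma family (sign-flipped for negative
#' skew), re-centered so the theoretical median equals the group's
#' `target_median` exactly; `spread` controls the standard deviation
#' and `skew` the asymmetry, emulating the skewed, heteroscedastic
#' distributions thermal assays produce. The same `(specs, seed)` pair
#' always returns an identical tibble.
#'
#' @param specs Data frame of group specifications, as built by
#'   [group_spec()] / [default_tolerance_specs()].
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return Tibble with columns `fly_id`, `treatment`, `sex`, `assay`,
#'   `value`, `unit`.
#' @examples
#' simulate_tolerance(default_tolerance_specs(), seed = 1)
#' @export
simulate_tolerance <- function(specs = default_tolerance_specs(), seed = NULL) {
  validate_group_specs(specs)
  with_seed(seed, {
    purrr::pmap(specs, function(treatment, sex, assay, target_median,
                                spread, skew, n, ...) {
      tibble::tibble(
        fly_id = sprintf("%s_%s_%s_%03d", assay, treatment, sex, seq_len(n)),
        treatment = treatment, sex = sex, assay = assay,
        value = draw_skewed(n, target_median, spread, skew),
        unit = assay_unit(assay)
      )
    }) |>
      purrr::list_rbind()
  })
}

# Beta-binomial draw: size trials per unit, mean p, intra-unit
# correlation rho. rho = 0 is plain binomial.
rbetabinom <- function(n, size, p, rho) {
  if (rho == 0 || p == 0 || p == 1) {
    return(rbinom(n, size, p))
  }
  shape1 <- p * (1 - rho) / rho
  shape2 <- (1 - p) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, shape1, shape2))
}

#' Simulate egg-to-adult viability vials
#'
#' Generates `vials_per_temp` vials of `eggs_per_vial` eggs at each
#' design temperature for each treatment. The number of emerging adults
#' is beta-binomial around the treatment's cubic-logistic curve with
#' intra-vial correlation `overdispersion_rho`; rho = 0 reduces exactly
#' to binomial sampling (the vial-count variance inflation factor is
#' 1 + (eggs - 1) * rho).
#'
#' @param specs A single [viability_curve_spec()] or a list of them
#'   (default the shipped two-treatment design).
#' @param seed Optional integer seed.
#' @return Tibble with columns `vial_id`, `treatment`, `temperature`,
#'   `eggs_set`, `adults_emerged`.
#' @examples
#' simulate_viability(default_viability_specs(), seed = 1)
#' @export
simulate_viability <- function(specs = default_viability_specs(), seed = NULL) {
  if (inherits(specs, "viability_curve_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, logical(1), "viability_curve_spec"))) {
    config_error("`specs` must be viability_curve_spec objects.")
  }
  with_seed(seed, {
    purrr::map(specs, function(sp) {
      probs <- viability_curve_prob(sp)
      if (any(probs < 0 | probs > 1 | !is.finite(probs))) {
        config_error("Curve probability outside [0, 1] at a listed temperature.")
      }
      purrr::map2(sp$temperatures, probs, function(tmp, p) {
        counts <- rbetabinom(sp$vials_per_temp, sp$eggs_per_vial, p,
                             sp$overdispersion_rho)
        tibble::tibble(
          vial_id = sprintf("%s_T%04.1f_v%02d", sp$treatment, tmp,
                            seq_len(sp$vials_per_temp)),
          treatment = sp$treatment, temperature = tmp,
          eggs_set = sp$eggs_per_vial, adults_emerged = counts
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
}

#' Simulate a microhabitat temperature log
#'
#' Produces half-hourly (by default) traces for an air sensor and two
#' heap sensors. Air follows a sinusoidal daily cycle around
#' `air_mean` (peaking mid-afternoon); each heap sensor adds the
#' fermentation offset and damps the daily amplitude by its damping
#' factor. Gaussian noise is added and readings are then quantized to
#' 0.1 C, as a data logger would record them.
#'
#' @param spec A [temperature_log_spec()].
#' @param seed Optional integer seed.
#' @return Tibble with columns `timestamp` (POSIXct, UTC), `sensor`
#'   (`"air"` plus the names of `amplitude_damping`), `temp_c`.
#' @examples
#' simulate_temperature_log(temperature_log_spec(), seed = 1)
#' @export
simulate_temperature_log <- function(spec = temperature_log_spec(), seed = NULL) {
  stopifnot(inherits(spec, "temperature_log_spec"))
  times <- seq(spec$start, spec$end, by = spec$interval_minutes * 60)
  secs_of_day <- as.numeric(times) %% 86400
  # daily cycle peaking at 15:00
  cycle <- sin(2 * pi * (secs_of_day - 32400) / 86400)
  quantize <- function(x) round(x, 1)
  with_seed(seed, {
    air <- tibble::tibble(
      timestamp = times, sensor = "air",
      temp_c = quantize(spec$air_mean + spec$air_daily_amplitude * cycle +
                          rnorm(length(times), 0, spec$noise_sd))
    )
    heaps <- purrr::imap(spec$amplitude_damping, function(damp, sensor_name) {
      tibble::tibble(
        timestamp = times, sensor = sensor_name,
        temp_c = quantize(spec$air_mean + spec$heap_offset +
                            damp * spec$air_daily_amplitude * cycle +
                            rnorm(length(times), 0, spec$noise_sd))
      )
    }) |> purrr::list_rbind()
    dplyr::bind_rows(air, heaps)
  })
}

# ---- CSV schemas ----------------------------------------------------------

#' Read and write the package's CSV schemas
#'
#' Plain headered, comma-separated, UTF-8 files. Tolerance files carry
#' one fly per row (`fly_id,treatment,sex,assay,value,unit`), viability
#' files one vial per row
#' (`vial_id,treatment,temperature,eggs_set,adults_emerged`), and
#' temperature logs one reading per row (`timestamp,sensor,temp_c`,
#' ISO-8601 timestamps).
#'
#' @param data Tibble in the matching schema.
#' @param path File path.
#' @return The tibble (readers), or `path` invisibly (writers).
#' @name tolerance_csv
NULL

#' @rdname tolerance_csv
#' @export
write_tolerance_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname tolerance_csv
#' @export
read_tolerance_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            fly_id = "c", treatment = "c", sex = "c",
                            assay = "c", value = "d", unit = "c"))
  if (any(!is.finite(data$value))) value_error("Non-finite tolerance values in file.")
  data
}

#' @rdname tolerance_csv
#' @export
write_viability_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname tolerance_csv
#' @export
read_viability_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            vial_id = "c", treatment = "c", temperature = "d",
                            eggs_set = "i", adults_emerged = "i"))
  validate_viability_records(data)
  data
}

#' @rdname tolerance_csv
#' @export
write_templog_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname tolerance_csv
#' @export
read_templog_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(timestamp = "T", sensor = "c",
                                          temp_c = "d"))
}

validate_viability_records <- function(data) {
  needed <- c("vial_id", "treatment", "temperature", "eggs_set", "adults_emerged")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    value_error(paste0("Viability data is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  bad <- data$adults_emerged < 0 | data$adults_emerged > data$eggs_set |
    data$eggs_set < 1
  if (any(bad | is.na(bad))) {
    value_error("Each vial needs 0 <= adults_emerged <= eggs_set and eggs_set >= 1.")
  }
  invisible(data)
}

# ---- configuration files --------------------------------------------------

#' Read a generator configuration from JSON or YAML
#'
#' The file may contain any of three top-level sections:
#' * `tolerance`: a list of group records with fields `treatment`,
#'   `sex`, `assay`, `target_median`, `spread`, `skew`, `n`;
#' * `viability`: a list of curve records with fields `treatment`,
#'   `coefficients` (length 4), `overdispersion_rho`, `temperatures`,
#'   `vials_per_temp`, `eggs_per_vial`, optional `constant_prob`;
#' * `templog`: fields of [temperature_log_spec()] (`start`/`end` as
#'   ISO-8601 strings).
#'
#' Missing sections fall back to the shipped defaults. Spreads and
#' skews have no published counterparts and are free parameters.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return Named list with elements `tolerance` (tibble of group
#'   specs), `viability` (list of curve specs), `templog`
#'   (temperature-log spec).
#' @export
read_synthetic_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  out <- list(tolerance = default_tolerance_specs(),
              viability = default_viability_specs(),
              templog = temperature_log_spec())
  if (!is.null(raw$tolerance)) {
    specs <- purrr::map(raw$tolerance, tibble::as_tibble) |> purrr::list_rbind()
    specs$n <- as.integer(specs$n)
    validate_group_specs(specs)
    out$tolerance <- specs
  }
  if (!is.null(raw$viability)) {
    out$viability <- purrr::map(raw$viability, function(v) {
      viability_curve_spec(
        treatment = v$treatment,
        coefficients = if (!is.null(v$coefficients)) unlist(v$coefficients),
        overdispersion_rho = v$overdispersion_rho %||% 0,
        temperatures = unlist(v$temperatures) %||%
          c(11, 14, 17, 20, 25, 27, 29, 31, 32, 33),
        vials_per_temp = v$vials_per_temp %||% 20L,
        eggs_per_vial = v$eggs_per_vial %||% 20L,
        constant_prob = v$constant_prob
      )
    })
  }
  if (!is.null(raw$templog)) {
    tl <- raw$templog
    defaults <- temperature_log_spec()
    out$templog <- temperature_log_spec(
      start = tl$start %||% defaults$start,
      end = tl$end %||% defaults$end,
      interval_minutes = tl$interval_minutes %||% defaults$interval_minutes,
      air_mean = tl$air_mean %||% defaults$air_mean,
      air_daily_amplitude = tl$air_daily_amplitude %||% defaults$air_daily_amplitude,
      heap_offset = tl$heap_offset %||% defaults$heap_offset,
      amplitude_damping = unlist(tl$amplitude_damping) %||% defaults$amplitude_damping,
      noise_sd = tl$noise_sd %||% defaults$noise_sd
    )
  }
  out
}
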