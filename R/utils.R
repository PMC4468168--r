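# Internal helpers: error classes, seed management, fast median.

config_error <- function(msg, ...) {
  abort(msg, class = "thermotol_config_error", ...)
}

value_error <- function(msg, ...) {
  abort(msg, class = "thermotol_value_error", ...)
}

fit_error <- function(msg, ...) {
  abort(msg, class = "thermotol_fit_error", ...)
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to an integer
#' seed in `[0, 2^31 - 2]`, so that every stochastic stage of a pipeline
#' run gets its own reproducible random stream, decoupled from the
#' order in which stages execute.
#'
#' Uses a 31-bit polynomial rolling hash of the label, seeded with the
#' master seed; no cryptographic strength is needed, only stability
#' across platforms and sessions.
#'
#' @param master Integer master seed.
#' @param stage Character label of the stage (e.g. `"perm/cold_ramp/female"`).
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "tolerance_data")
#' @export
derive_seed <- function(master, stage) {
  if (length(master) != 1L || is.na(master) || master %% 1 != 0) {
    config_error("`master` must be a single integer seed.")
  }
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Median without S3 dispatch; hot path of the permutation loop.
fast_median <- function(x) {
  n <- length(x)
  half <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort(x, partial = half)[half]
  } else {
    s <- sort(x, partial = c(half, half + 1L))
    (s[half] + s[half + 1L]) / 2
  }
}

check_finite_numeric <- function(x, arg) {
  if (!is.numeric(x) || length(x) == 0L) {
    value_error(sprintf("`%s` must be a non-empty numeric vector.", arg))
  }
  if (any(!is.finite(x))) {
    value_error(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
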