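#' @importFrom jsonlite read_json write_json
#' @importFrom stats approxfun uniroot runif rnorm setNames
#' @importFrom utils read.csv write.csv head packageVersion
#' @importFrom deSolve ode lsodar
#' @importFrom pracma charpoly
NULL

# Internal: read the packaged kinetic-constant registry once per session.
.registry_env <- new.env(parent = emptyenv())

.read_registry <- function() {
  if (is.null(.registry_env$fixture)) {
    path <- system.file("extdata", "kinetic_parameters.json", package = "floradyn")
    .registry_env$fixture <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .registry_env$fixture
}

#' Admissible parameter ranges
#'
#' The ranges within which the kinetic constants were estimated and within
#' which random draws are taken: maximum transcription rates `beta` in
#' \[0.001, 200\] nM/min, half-max abundances `K` in \[0.001, 2000\] nM,
#' degradation rates `d` in \[0.001, 1\] /min, and the transport delay in
#' \[0, 1\] days.
#'
#' @return Named list of two-element numeric ranges.
#' @export
parameter_ranges <- function() {
  r <- .read_registry()$ranges
  lapply(r, as.numeric)
}

#' Kinetic parameter set of the flowering network
#'
#' Builds the registry of the 34 kinetic constants of the six-gene model
#' (12 maximum transcription rates `beta`, 16 half-max abundances `K`, 6
#' degradation rates `d`) together with the FT transport delay and the Hill
#' cooperativity `n`. Defaults are the published point estimates; individual
#' entries can be overridden by name (e.g. `beta1`, `K4`, `d2`,
#' `delta_days`, `n`) or loaded from a JSON configuration file with the same
#' keys.
#'
#' All rates are in per-minute units internally; the delay is stored both in
#' days (as printed) and minutes (as used by the integrator).
#'
#' @param overrides Named list of replacement values, or `NULL`.
#' @param file Optional path to a JSON file whose top level (or `values`
#'   field) holds named overrides.
#' @param validate If `TRUE` (default) check positivity and that values lie
#'   inside the admissible ranges.
#' @return An object of class `grn_parameters`: list with numeric vectors
#'   `beta` (12), `K` (16), `d` (6), scalars `delta_days`, `delta_min`, `n`.
#' @examples
#' p <- flowering_parameters()
#' p$beta[1]                       # 99.8 nM/min
#' flowering_parameters(list(beta4 = 30))$beta[4]
#' @export
flowering_parameters <- function(overrides = NULL, file = NULL, validate = TRUE) {
  vals <- .read_registry()$values
  if (!is.null(file)) {
    cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
    if (!is.null(cfg$values)) cfg <- cfg$values
    overrides <- c(cfg, overrides)
  }
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("parameter overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(vals))
    if (length(unknown)) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    }
    vals[names(overrides)] <- overrides
  }
  v <- unlist(vals)
  p <- structure(list(
    beta = unname(v[paste0("beta", 1:12)]),
    K = unname(v[paste0("K", 1:16)]),
    d = unname(v[paste0("d", 1:6)]),
    delta_days = unname(v[["delta_days"]]),
    delta_min = unname(v[["delta_days"]]) * 1440,
    n = as.integer(v[["n"]])
  ), class = "grn_parameters")
  if (validate) validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks strict positivity of all kinetic constants, integrality of the
#' Hill exponent, and (for the rates and abundances) membership of the
#' admissible estimation ranges. The delay may be zero.
#'
#' @param p A `grn_parameters` object.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "grn_parameters"))
  if (length(p$beta) != 12 || length(p$K) != 16 || length(p$d) != 6) {
    stop("parameter set must contain 12 beta, 16 K and 6 d entries")
  }
  if (any(!is.finite(c(p$beta, p$K, p$d))) || any(c(p$beta, p$K, p$d) <= 0)) {
    stop("all kinetic constants must be finite and strictly positive")
  }
  if (p$n < 1 || p$n != round(p$n)) stop("Hill exponent n must be a positive integer")
  if (p$delta_days < 0) stop("delay must be non-negative")
  r <- parameter_ranges()
  chk <- function(x, rng, what) {
    if (any(x < rng[1] - 1e-12) || any(x > rng[2] + 1e-12)) {
      stop(sprintf("%s outside the admissible range [%g, %g]", what, rng[1], rng[2]))
    }
  }
  chk(p$beta, r$beta, "maximum transcription rate")
  chk(p$K, r$K, "half-max abundance")
  chk(p$d, r$d, "degradation rate")
  chk(p$delta_days, r$delta_days, "delay (days)")
  invisible(TRUE)
}

#' @export
print.grn_parameters <- function(x, ...) {
  cat("Flowering-network parameter set\n")
  cat("  beta (nM/min):", paste(signif(x$beta, 4), collapse = " "), "\n")
  cat("  K (nM):       ", paste(signif(x$K, 4), collapse = " "), "\n")
  cat("  d (1/min):    ", paste(signif(x$d, 4), collapse = " "), "\n")
  cat(sprintf("  delay: %g days (%g min), Hill n = %d\n", x$delta_days, x$delta_min, x$n))
  invisible(x)
}

#' Constant external input signals
#'
#' The four external inputs of the network -- SVP and FLC expression in the
#' meristem (`x7`, `x8`) and in the leaves (`x9`, `x10`) -- held at fixed
#' levels. This is the mode assumed throughout the steady-state analysis.
#'
#' @param x7,x8,x9,x10 Non-negative concentrations (nM).
#' @return A `grn_inputs` object in `"constant"` mode.
#' @seealso [default_input_levels()] for the packaged calibrated levels,
#'   [piecewise_inputs()] for time-varying signals.
#' @export
constant_inputs <- function(x7, x8, x9, x10) {
  v <- c(x7 = x7, x8 = x8, x9 = x9, x10 = x10)
  if (any(!is.finite(v)) || any(v < 0)) stop("input levels must be finite and non-negative")
  structure(list(mode = "constant", levels = v), class = "grn_inputs")
}

#' Piecewise-linear external input signals
#'
#' Time-varying input signals, linearly interpolated between knots, emulating
#' expression time courses interpolated from experimental data. Values are
#' held at the boundary knots outside the knot range.
#'
#' @param times_min Increasing vector of knot times (min).
#' @param values Matrix (or data frame) with one column per input
#'   (`x7`, `x8`, `x9`, `x10`) and one row per knot; all non-negative.
#' @return A `grn_inputs` object in `"piecewise"` mode.
#' @export
piecewise_inputs <- function(times_min, values) {
  values <- as.matrix(values)
  if (ncol(values) != 4) stop("'values' must have four columns (x7, x8, x9, x10)")
  if (nrow(values) != length(times_min)) stop("one row of values per knot time required")
  if (is.unsorted(times_min, strictly = TRUE)) stop("knot times must be strictly increasing")
  if (any(values < 0)) stop("input signals must be non-negative")
  colnames(values) <- c("x7", "x8", "x9", "x10")
  funs <- lapply(1:4, function(j) {
    if (length(times_min) == 1) {
      v <- values[1, j]
      function(t) rep(v, length(t))
    } else {
      stats::approxfun(times_min, values[, j], rule = 2)
    }
  })
  structure(list(mode = "piecewise", times_min = times_min, values = values,
                 funs = funs), class = "grn_inputs")
}

#' Packaged constant input levels
#'
#' Returns the packaged constant levels for the four external inputs. These
#' are synthetic stand-ins: the experimental constant levels are not
#' redistributable, so the packaged values are calibrated such that the
#' inhibition products `kappa11*kappa12` and `kappa15*kappa16` reproduce the
#' published positive steady state of the full network exactly (see the
#' methods vignette).
#'
#' @return A `grn_inputs` object in `"constant"` mode.
#' @export
default_input_levels <- function() {
  path <- system.file("extdata", "input_levels_synthetic.json", package = "floradyn")
  v <- jsonlite::read_json(path, simplifyVector = TRUE)$values
  constant_inputs(v$x7, v$x8, v$x9, v$x10)
}

#' Evaluate input signals at given times
#'
#' @param inputs A `grn_inputs` object.
#' @param t Time(s) in minutes.
#' @return For scalar `t`, a named numeric vector `(x7, x8, x9, x10)`; for
#'   vector `t`, a matrix with one row per time.
#' @export
eval_inputs <- function(inputs, t) {
  stopifnot(inherits(inputs, "grn_inputs"))
  if (inputs$mode == "constant") {
    if (length(t) == 1) return(inputs$levels)
    return(matrix(inputs$levels, nrow = length(t), ncol = 4, byrow = TRUE,
                  dimnames = list(NULL, names(inputs$levels))))
  }
  m <- vapply(inputs$funs, function(f) f(t), numeric(length(t)))
  if (length(t) == 1) return(stats::setNames(as.numeric(m), c("x7", "x8", "x9", "x10")))
  colnames(m) <- c("x7", "x8", "x9", "x10")
  m
}

#' @export
print.grn_inputs <- function(x, ...) {
  if (x$mode == "constant") {
    cat("Constant external inputs (nM):",
        paste(sprintf("%s=%.6g", names(x$levels), x$levels), collapse = ", "), "\n")
  } else {
    cat(sprintf("Piecewise-linear external inputs: %d knots on [%g, %g] min\n",
                length(x$times_min), min(x$times_min), max(x$times_min)))
  }
  invisible(x)
}
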