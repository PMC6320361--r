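# Synthetic-data generators standing in for the study's experimental
# inputs: piecewise-linear input time courses (the experimental signals
# were linearly interpolated) and random parameter draws within the
# estimation ranges.

#' Generator specification
#'
#' @param seed Integer seed; all generator output is a pure function of it.
#' @param mode `"constant"` (fixed levels) or `"piecewise"` (piecewise-
#'   linear time courses).
#' @param knots Number of interpolation knots per signal (1 forces constant
#'   signals).
#' @param horizon_days Time span covered by piecewise signals.
#' @param input_ranges Named list (`x7`, `x8`, `x9`, `x10`) of two-element
#'   ranges (nM) from which signal values are drawn; defaults to
#'   `[0, 2 * packaged level]` per input.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1, mode = c("piecewise", "constant"),
                           knots = 5, horizon_days = 100,
                           input_ranges = NULL) {
  mode <- match.arg(mode)
  if (knots < 1) stop("at least one knot is required")
  if (is.null(input_ranges)) {
    lev <- default_input_levels()$levels
    input_ranges <- lapply(as.list(lev), function(v) c(0, 2 * v))
    names(input_ranges) <- names(lev)
  }
  for (r in input_ranges) {
    if (length(r) != 2 || r[2] < r[1] || r[1] < 0) {
      stop("each input range must be a non-negative interval")
    }
  }
  structure(list(seed = as.integer(seed), mode = mode, knots = as.integer(knots),
                 horizon_days = horizon_days, input_ranges = input_ranges),
            class = "generator_spec")
}

#' Generate external input signals
#'
#' Draws the four input signals independently. In piecewise mode each
#' signal takes uniformly drawn values at equally spaced knots over the
#' horizon and is linearly interpolated between them (held constant outside
#' the knot range), emulating expression time courses interpolated from
#' sampled data; in constant mode (or with a single knot) each signal is a
#' fixed level drawn from its range.
#'
#' @param spec A `generator_spec`.
#' @return A `grn_inputs` object.
#' @export
generate_inputs <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  draw <- function(rng, k) stats::runif(k, rng[1], rng[2])
  if (spec$mode == "constant" || spec$knots == 1) {
    v <- vapply(spec$input_ranges, draw, numeric(1), k = 1)
    return(constant_inputs(v[["x7"]], v[["x8"]], v[["x9"]], v[["x10"]]))
  }
  times <- seq(0, spec$horizon_days * 1440, length.out = spec$knots)
  vals <- vapply(spec$input_ranges, draw, numeric(spec$knots), k = spec$knots)
  piecewise_inputs(times, vals)
}

#' Draw a random parameter set
#'
#' Log-uniform draws of the 34 kinetic constants within the estimation
#' ranges (the ranges span up to five decades, so uniform-in-log sampling
#' spreads draws across scales), a uniform delay within its range, and the
#' Hill exponent fixed at 3. Every draw passes parameter validation.
#'
#' @param spec A `generator_spec` (only the seed is used).
#' @return A validated `grn_parameters` object.
#' @export
draw_parameters <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 1L)    # distinct stream from the input-signal draws
  r <- parameter_ranges()
  logu <- function(rng, k) {
    if (rng[1] == rng[2]) return(rep(rng[1], k))
    exp(stats::runif(k, log(rng[1]), log(rng[2])))
  }
  ov <- c(as.list(stats::setNames(logu(r$beta, 12), paste0("beta", 1:12))),
          as.list(stats::setNames(logu(r$K, 16), paste0("K", 1:16))),
          as.list(stats::setNames(logu(r$d, 6), paste0("d", 1:6))),
          list(delta_days = stats::runif(1, r$delta_days[1], r$delta_days[2]),
               n = 3))
  flowering_parameters(overrides = ov)
}
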