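#' Local parameter sensitivity of a steady-state output
#'
#' Normalised central-difference sensitivities
#' `S_q = (q / y) * dy/dq ~ (y(q+) - y(q-)) / (2 * rel * y)` of a scalar
#' output with respect to each of the 34 kinetic constants (the delay does
#' not enter the steady state and the Hill exponent is structural). The
#' default output is the AP1 component of the unique positive steady state
#' of the full model. Parameters under which the positive steady state is
#' lost are flagged and left unranked.
#'
#' @param p A `grn_parameters` object (the nominal point).
#' @param inputs Constant-mode `grn_inputs`.
#' @param output Function `(p, inputs) -> scalar`; defaults to the
#'   positive-steady-state AP1 level.
#' @param rel_perturbation Relative perturbation (default 1 %).
#' @return Object of class `grn_sensitivity`: data frame with columns
#'   `parameter`, `S`, `rank` (by decreasing `|S|`; `NA` for flagged
#'   parameters), plus the perturbation size as an attribute.
#' @export
local_sensitivity <- function(p, inputs, output = NULL,
                              rel_perturbation = 0.01) {
  stopifnot(inherits(p, "grn_parameters"))
  base_hint <- NULL
  if (is.null(output)) {
    base <- solve_full_steady_state(p, inputs)
    base <- Filter(function(s) s$positive, base)
    if (length(base) != 1) stop("nominal positive steady state not unique")
    base_hint <- base[[1]]$state[["SOC1"]]
    output <- function(pp, ii) {
      ss <- solve_full_steady_state(pp, ii, x3_hint = base_hint)
      ss <- Filter(function(s) s$positive, ss)
      if (!length(ss)) return(NA_real_)
      ss[[which.max(vapply(ss, function(s) s$state[["AP1"]], 0))]]$state[["AP1"]]
    }
  }
  y0 <- output(p, inputs)
  if (!is.finite(y0) || y0 == 0) stop("output not evaluable at the nominal parameters")

  nm <- c(paste0("beta", 1:12), paste0("K", 1:16), paste0("d", 1:6))
  S <- vapply(nm, function(q) {
    yp <- output(.perturb(p, q, 1 + rel_perturbation), inputs)
    ym <- output(.perturb(p, q, 1 - rel_perturbation), inputs)
    if (!is.finite(yp) || !is.finite(ym)) return(NA_real_)
    (yp - ym) / (2 * rel_perturbation * y0)
  }, 0)
  rk <- rep(NA_integer_, length(S))
  ok <- which(is.finite(S))
  rk[ok[order(-abs(S[ok]))]] <- seq_along(ok)
  out <- data.frame(parameter = nm, S = unname(S), rank = rk)
  structure(out, class = c("grn_sensitivity", "data.frame"),
            rel_perturbation = rel_perturbation)
}

# scale a single named parameter by `factor` (bypasses range validation:
# perturbations may step marginally outside the estimation ranges)
.perturb <- function(p, name, factor) {
  q <- p
  if (grepl("^beta", name)) {
    i <- as.integer(sub("beta", "", name)); q$beta[i] <- q$beta[i] * factor
  } else if (grepl("^K", name)) {
    i <- as.integer(sub("K", "", name)); q$K[i] <- q$K[i] * factor
  } else if (grepl("^d", name)) {
    i <- as.integer(sub("d", "", name)); q$d[i] <- q$d[i] * factor
  } else stop("unknown parameter: ", name)
  q
}

#' Transition-phase AP1 output for sensitivity analysis
#'
#' Builds a scalar output functional that evaluates the AP1 level at the
#' nominal trajectory's half-rise time (the moment AP1 first reaches half
#' its equilibrium level). At equilibrium the cooperative LFY -> AP1 Hill
#' term is deeply saturated, so steady-state outputs are blind to the
#' switching constants (`K1` in particular); probing the transition phase
#' instead exposes the mutual-activation loop (`beta1`, `K1`, `beta4`,
#' `K4`, `beta5`, `K5`, `d1`) that controls flowering onset.
#'
#' @param p Nominal `grn_parameters` (defines the half-rise time).
#' @param inputs Constant-mode `grn_inputs`.
#' @param step_min Integration step (min) for the underlying simulations.
#' @return Function `(p, inputs) -> AP1 (nM)` suitable as the `output`
#'   argument of [local_sensitivity()].
#' @export
ap1_transition_output <- function(p, inputs, step_min = 0.5) {
  ss <- solve_full_steady_state(p, inputs)
  ss <- Filter(function(s) s$positive, ss)
  if (length(ss) != 1) stop("nominal positive steady state not unique")
  target <- 0.5 * ss[[1]]$state[["AP1"]]
  probe <- simulate_full(p, inputs, horizon_days = 2, step_min = step_min)
  i <- which(probe$AP1 >= target)[1]
  if (is.na(i)) stop("AP1 does not reach half its equilibrium within the probe horizon")
  t_half <- probe$time_min[i]
  horizon <- max(3 * t_half, 120) / 1440
  function(pp, ii) {
    tr <- simulate_full(pp, ii, horizon_days = horizon, step_min = step_min)
    tr$AP1[which.min(abs(tr$time_min - t_half))]
  }
}

#' Top-ranked parameters of a sensitivity report
#'
#' @param sens A `grn_sensitivity` object.
#' @param k How many top ranks to return.
#' @return Character vector of parameter names, most influential first.
#' @export
top_parameters <- function(sens, k = 10) {
  ord <- sens$parameter[order(sens$rank, na.last = NA)]
  utils::head(ord, k)
}
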