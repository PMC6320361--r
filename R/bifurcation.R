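# Saddle-node analysis of the AP1/LFY motif in the (F1, F2) action plane,
# nullclines, basin classification and flowering-time computation.

#' Cubic discriminant of the motif steady-state polynomial
#'
#' `Delta3 = omega4 * (4*(omega3*F1*F2)^3 - 27*(omega1 + omega2*F2)^2 *
#' omega4)`. Two strictly positive equilibria exist iff `Delta3 > 0`;
#' `Delta3 = 0` is the saddle-node (double-root) locus.
#'
#' @param mp A `grn_motif` object (with `n = 3`), or parameters from which
#'   one is built via `motif_params`.
#' @param F1,F2 Optional action-factor overrides.
#' @return The discriminant value (scalar).
#' @export
cubic_discriminant <- function(mp, F1 = mp$F1, F2 = mp$F2) {
  stopifnot(inherits(mp, "grn_motif"))
  if (mp$n != 3) stop("discriminant analysis requires n = 3")
  w <- mp$omega
  w[4] * (4 * (w[3] * F1 * F2)^3 - 27 * (w[1] + w[2] * F2)^2 * w[4])
}

#' Critical action factor for existence of positive motif equilibria
#'
#' Solves the saddle-node condition `Delta3 = 0` by bisection for the three
#' canonical scenarios: `"subsystem1"` (FT action on AP1 only, `F1 = 1`,
#' solve for `F2`), `"subsystem2"` (FT-FD action on LFY only, `F2 = 1`,
#' solve for `F1`), and `"subsystem3"` (equal action, `F1 = F2 = F`). Below
#' the critical value no positive equilibrium exists; above it a stable and
#' an unstable branch emanate from the double root.
#'
#' @param scenario One of `"subsystem1"`, `"subsystem2"`, `"subsystem3"`.
#' @param p A `grn_parameters` object supplying the motif constants.
#' @param bracket Search interval for the free factor.
#' @param tol Absolute bisection tolerance on F.
#' @return Object of class `grn_bifurcation`: scenario, `F_critical`, the
#'   bracket and tolerance, the double LFY root at criticality and its
#'   multiplicity.
#' @export
find_critical_F <- function(scenario = c("subsystem1", "subsystem2", "subsystem3"),
                            p = flowering_parameters(),
                            bracket = c(1e-4, 10), tol = 1e-7) {
  scenario <- match.arg(scenario)
  g <- function(F) {
    mp <- switch(scenario,
                 subsystem1 = motif_params(p, F1 = 1, F2 = F),
                 subsystem2 = motif_params(p, F1 = F, F2 = 1),
                 subsystem3 = motif_params(p, F1 = F, F2 = F))
    cubic_discriminant(mp)
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- g(lo); fhi <- g(hi)
  if (sign(flo) == sign(fhi)) {
    stop("no sign change of the discriminant on the bracket (",
         lo, ", ", hi, ")")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- g(mid)
    if (fm == 0) { lo <- hi <- mid; break }
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  Fc <- (lo + hi) / 2
  mp <- switch(scenario,
               subsystem1 = motif_params(p, F1 = 1, F2 = Fc),
               subsystem2 = motif_params(p, F1 = Fc, F2 = 1),
               subsystem3 = motif_params(p, F1 = Fc, F2 = Fc))
  w <- mp$omega
  dbl <- 2 * w[3] * mp$F1 * mp$F2 / (3 * (w[1] + w[2] * mp$F2))
  structure(list(scenario = scenario, F_critical = Fc, bracket = bracket,
                 tol = tol, lfy_double_root = dbl, multiplicity = 2L),
            class = "grn_bifurcation")
}

#' @export
print.grn_bifurcation <- function(x, ...) {
  cat(sprintf("Saddle-node of the AP1/LFY motif (%s): F = %.6f\n",
              x$scenario, x$F_critical))
  cat(sprintf("  double LFY root %.6g nM, bisection tol %g\n",
              x$lfy_double_root, x$tol))
  invisible(x)
}

#' Motif nullclines in the (LFY, AP1) plane
#'
#' Samples both sides of the equilibrium relation: the AP1 nullcline
#' `AP1 = beta1*F2/d1 * LFY^n/(LFY^n + K1^n)` and the LFY nullcline
#' `AP1 = d2*K4*LFY / (beta4*F1 - d2*LFY)` (defined below the existence
#' bound `LFY < beta4*F1/d2`). Intersections are located by sign changes of
#' the difference and agree with the positive roots of the steady-state
#' cubic.
#'
#' @param mp A `grn_motif` object.
#' @param x2_range LFY range (nM) to sample; truncated with a warning at
#'   the existence bound.
#' @param n_points Number of sample points.
#' @return List with data frame `curves` (`LFY`, `ap1_nullcline`,
#'   `lfy_nullcline`) and numeric `intersections` (LFY values).
#' @export
nullclines <- function(mp, x2_range = NULL, n_points = 2000) {
  stopifnot(inherits(mp, "grn_motif"))
  bound <- mp$beta4 * mp$F1 / mp$d2
  if (is.null(x2_range)) x2_range <- c(0, 0.999 * bound)
  if (x2_range[2] >= bound) {
    warning("LFY range truncated at the existence bound beta4*F1/d2")
    x2_range[2] <- 0.999 * bound
  }
  x2 <- seq(x2_range[1], x2_range[2], length.out = n_points)
  lhs <- mp$beta1 * mp$F2 / mp$d1 * hill_activation(x2, mp$K1, mp$n)
  rhs <- mp$d2 * mp$K4 * x2 / (mp$beta4 * mp$F1 - mp$d2 * x2)
  diffc <- lhs - rhs
  idx <- which(diff(sign(diffc)) != 0)
  inter <- vapply(idx, function(i) {
    stats::uniroot(function(z) {
      mp$beta1 * mp$F2 / mp$d1 * hill_activation(z, mp$K1, mp$n) -
        mp$d2 * mp$K4 * z / (mp$beta4 * mp$F1 - mp$d2 * z)
    }, c(x2[i], x2[i + 1]), tol = 1e-10)$root
  }, 0)
  inter <- inter[inter > 1e-12]    # drop the trivial crossing at the origin
  list(curves = data.frame(LFY = x2, ap1_nullcline = lhs, lfy_nullcline = rhs),
       intersections = inter)
}

# stable/unstable equilibria of the motif in (AP1, LFY) coordinates
.motif_equilibria <- function(mp) {
  cb <- motif_cubic(mp)
  states <- list(trivial = c(AP1 = 0, LFY = 0))
  verdicts <- c(trivial = "stable")
  if (cb$positive_count == 2) {
    for (i in seq_along(cb$positive_roots)) {
      x2 <- cb$positive_roots[i]
      x1 <- map_equilibrium_relations(x2, mp)$AP1
      lab <- if (i == 1) "saddle" else "flowering"
      states[[lab]] <- c(AP1 = x1, LFY = x2)
      verdicts[lab] <- motif_stability(x2, mp)
    }
  }
  list(states = states, verdicts = verdicts, cubic = cb)
}

#' Classify the basin of attraction of a motif initial condition
#'
#' Integrates the motif from the initial condition and labels the endpoint:
#' `"flowering"` if it settles at the non-trivial stable state, `"trivial"`
#' if at the origin, `"unresolved"` if the trajectory is still in transit at
#' the horizon. Proximity is relative (1 %) with a 0.01 nM absolute floor.
#'
#' @param initial Length-2 initial state (`AP1, LFY`), nM.
#' @param mp A `grn_motif` object.
#' @param horizon_days Integration horizon (days).
#' @param eps_rel,eps_floor Relative tolerance and absolute floor (nM) for
#'   endpoint proximity.
#' @return One of `"trivial"`, `"flowering"`, `"unresolved"`.
#' @export
classify_basin <- function(initial, mp, horizon_days = 100,
                           eps_rel = 0.01, eps_floor = 0.01) {
  eq <- .motif_equilibria(mp)
  tr <- simulate_motif(mp, initial, horizon_days = horizon_days,
                       step_min = 60)
  endp <- c(tr$AP1[nrow(tr)], tr$LFY[nrow(tr)])
  near <- function(target) {
    all(abs(endp - target) <= pmax(eps_rel * abs(target), eps_floor))
  }
  stable <- names(eq$verdicts)[eq$verdicts == "stable"]
  for (lab in stable) {
    if (near(eq$states[[lab]])) {
      return(if (lab == "trivial") "trivial" else "flowering")
    }
  }
  "unresolved"
}

#' Flowering time of the AP1/LFY motif
#'
#' Integrates the motif from `(AP1_0, LFY_0)` and reports the first time at
#' which AP1 reaches a threshold fraction (default 50 %) of the non-trivial
#' stable AP1 equilibrium -- the operational definition of flowering onset.
#' Uses `deSolve` (lsodar) with a root function so the crossing is located
#' by the integrator.
#'
#' @param initial Length-2 initial state (`AP1, LFY`), nM.
#' @param mp A `grn_motif` object; must admit a non-trivial stable state.
#' @param horizon_days Horizon (days).
#' @param threshold_frac Fraction of the stable AP1 level defining onset.
#' @return Flowering time in days, or `Inf` if the threshold is not reached
#'   within the horizon (no flowering).
#' @export
flowering_time <- function(initial, mp, horizon_days = 100,
                           threshold_frac = 0.5) {
  stopifnot(length(initial) == 2, horizon_days > 0)
  eq <- .motif_equilibria(mp)
  if (!"flowering" %in% names(eq$states) ||
      eq$verdicts[["flowering"]] != "stable") {
    stop("no positive stable equilibrium exists for these action factors")
  }
  thr <- threshold_frac * eq$states$flowering[["AP1"]]
  if (initial[1] >= thr) return(0)
  times <- c(0, horizon_days * 1440)
  out <- deSolve::lsodar(y = as.numeric(initial), times = times,
                         func = function(t, y, parms) list(motif_rhs(t, pmax(y, 0), mp)),
                         parms = NULL,
                         rootfunc = function(t, y, parms) y[1] - thr, hmax = 1440)
  troot <- attr(out, "troot")
  if (is.null(troot) || !length(troot)) return(Inf)
  troot[1] / 1440
}

#' Smallest flowering initial LFY level on a grid
#'
#' Scans initial LFY values on a grid (fixed initial AP1) and returns the
#' smallest one from which the motif flowers within the horizon, together
#' with the per-grid-point flowering times.
#'
#' @param mp A `grn_motif` object.
#' @param ap1_0 Initial AP1 (nM).
#' @param lfy_grid Grid of initial LFY values (nM).
#' @param horizon_days Horizon (days).
#' @param threshold_frac Flowering-onset fraction (see [flowering_time()]).
#' @return List with `threshold` (smallest flowering LFY, `NA` if none) and
#'   data frame `profile` (`LFY0`, `flowering_time_days`).
#' @export
flowering_threshold <- function(mp, ap1_0 = 0.24,
                                lfy_grid = seq(1.20, 1.30, by = 0.01),
                                horizon_days = 100, threshold_frac = 0.5) {
  ft <- vapply(lfy_grid, function(l) {
    flowering_time(c(ap1_0, l), mp, horizon_days, threshold_frac)
  }, 0)
  ok <- which(is.finite(ft))
  list(threshold = if (length(ok)) lfy_grid[min(ok)] else NA_real_,
       profile = data.frame(LFY0 = lfy_grid, flowering_time_days = ft))
}
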