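# Steady-state solvers. The full system is reduced to a scalar equation in
# the SOC1 level: FT is explicit from the inputs, FD and AGL24 are explicit
# in LFY and SOC1, AP1 is explicit in LFY and FD, and the LFY balance is a
# monotone scalar equation solvable for each trial SOC1. The remaining SOC1
# balance is bracketed on a log grid and polished.

.steady_state <- function(state, residual, tol = 1e-8, multiplicity = 1L) {
  structure(list(state = state,
                 residual = residual,
                 positive = all(state > 0),
                 multiplicity = multiplicity),
            class = "grn_steady_state")
}

#' @export
print.grn_steady_state <- function(x, ...) {
  cat("Steady state (nM):",
      paste(sprintf("%s=%.6g", names(x$state), x$state), collapse = ", "), "\n")
  cat(sprintf("  residual %.3g, %s\n", x$residual,
              if (x$positive) "strictly positive" else "not strictly positive"))
  invisible(x)
}

# Inner solve: LFY balance for a given SOC1 level (and its AGL24 image).
# The left side d2*x2 grows without bound while the production side is
# bounded by beta4+beta5+beta6, so a single root exists on [0, upper].
.solve_lfy <- function(x3, p, u) {
  b <- p$beta; K <- p$K; d <- p$d
  x5 <- b[11] * hill_activation(x3, K[14]) / d[5]
  fixed <- b[5] * hill_activation(x3, K[5]) + b[6] * hill_activation(x5, K[6])
  f <- function(x2) {
    x4 <- b[10] * hill_activation(x2, K[13]) / d[4]
    x1 <- (b[1] * hill_activation(x2, K[1], p$n) + b[2] * hill_activation(x4, K[2]) +
             b[3] * hill_activation(u, K[3])) / d[1]
    d[2] * x2 - (b[4] * hill_activation(x1, K[4]) + fixed)
  }
  if (f(0) >= 0) return(0)
  upper <- (b[4] + b[5] + b[6]) / d[2] * (1 + 1e-9) + 1e-12
  stats::uniroot(f, c(0, upper), tol = 1e-13)$root
}

# SOC1 balance residual given a trial SOC1 level.
.soc1_residual <- function(x3, p, u, kprod) {
  b <- p$beta; K <- p$K; d <- p$d
  x5 <- b[11] * hill_activation(x3, K[14]) / d[5]
  x2 <- .solve_lfy(x3, p, u)
  x4 <- b[10] * hill_activation(x2, K[13]) / d[4]
  d[3] * x3 - (b[7] * hill_activation(x3, K[7]) + b[8] * hill_activation(x5, K[8]) +
                 b[9] * hill_activation(x4, K[9]) * hill_activation(u, K[10])) * kprod
}

.assemble_state <- function(x3, p, u) {
  b <- p$beta; K <- p$K; d <- p$d
  x5 <- b[11] * hill_activation(x3, K[14]) / d[5]
  x2 <- .solve_lfy(x3, p, u)
  x4 <- b[10] * hill_activation(x2, K[13]) / d[4]
  x1 <- (b[1] * hill_activation(x2, K[1], p$n) + b[2] * hill_activation(x4, K[2]) +
           b[3] * hill_activation(u, K[3])) / d[1]
  stats::setNames(c(x1, x2, x3, x4, x5, u), .state_names6)
}

#' Solve for steady states of the full six-gene model
#'
#' Computes the constant FT level directly from the inputs, reduces the
#' remaining equilibrium conditions to a scalar equation in the SOC1 level,
#' brackets sign changes on a dense log-spaced grid and polishes each root.
#' Every returned state is verified against the full right-hand side.
#'
#' @param p A `grn_parameters` object.
#' @param inputs Constant-mode `grn_inputs`.
#' @param bracket Search interval for the SOC1 level (nM).
#' @param grid_size Number of log-spaced bracketing points.
#' @param x3_hint Optional approximate SOC1 level; when given, the search is
#'   restricted to `(hint/4, 4*hint)` (used by the sensitivity scan).
#' @param tol Residual tolerance (relative, on the rate vector).
#' @return List of `grn_steady_state` objects (possibly empty).
#' @export
solve_full_steady_state <- function(p, inputs, bracket = c(1e-6, 1e6),
                                    grid_size = 2000, x3_hint = NULL,
                                    tol = 1e-8) {
  stopifnot(inherits(p, "grn_parameters"))
  if (!inherits(inputs, "grn_inputs") || inputs$mode != "constant") {
    stop("steady-state analysis requires constant inputs")
  }
  b <- p$beta; K <- p$K; d <- p$d
  lv <- inputs$levels
  u <- b[12] * hill_inhibition(lv[["x9"]], K[15]) *
    hill_inhibition(lv[["x10"]], K[16]) / d[6]
  kprod <- hill_inhibition(lv[["x7"]], K[11]) * hill_inhibition(lv[["x8"]], K[12])

  if (!is.null(x3_hint)) {
    bracket <- c(max(bracket[1], x3_hint / 4), min(bracket[2], x3_hint * 4))
    grid_size <- min(grid_size, 200)
  }
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = grid_size))
  res <- vapply(grid, .soc1_residual, 0, p = p, u = u, kprod = kprod)

  roots <- numeric(0)
  # boundary root at SOC1 -> 0 (pure-decay degenerate case)
  if (abs(.soc1_residual(0, p, u, kprod)) < 1e-12) roots <- 0
  idx <- which(diff(sign(res)) != 0)
  for (i in idx) {
    r <- stats::uniroot(.soc1_residual, c(grid[i], grid[i + 1]), p = p, u = u,
                        kprod = kprod, tol = 1e-12)$root
    roots <- c(roots, r)
  }
  if (!length(roots)) {
    message("no steady-state bracket found on (", bracket[1], ", ", bracket[2], ")")
    return(list())
  }
  roots <- roots[!duplicated(signif(roots, 10))]
  lapply(roots, function(r) {
    st <- .assemble_state(r, p, u)
    rate <- full_rhs(0, st, st[6], p, inputs)
    .steady_state(st, max(abs(rate) / pmax(abs(st), 1)))
  })
}

#' Solve for steady states of the reduced three-gene model
#'
#' Same scalar-reduction strategy as the full model, applied to the reduced
#' AP1/LFY/SOC1 system: AP1 is explicit in LFY, the LFY balance is solved
#' for each trial SOC1 level, and the SOC1 balance is bracketed and polished.
#'
#' @param p A `grn_parameters` object.
#' @param inputs Constant-mode `grn_inputs` or a `grn_derived` object.
#' @param bracket,grid_size Search interval and resolution for SOC1.
#' @return List of `grn_steady_state` objects.
#' @export
solve_reduced_steady_state <- function(p, inputs, bracket = c(1e-6, 1e6),
                                       grid_size = 2000) {
  dc <- if (inherits(inputs, "grn_derived")) inputs else derive_constants(p, inputs)
  V <- dc$V; S <- dc$S; d <- p$d
  x1_of <- function(x2) (V[1] * x2^3 / (x2^3 + S[1]^3) +
                           V[2] * x2 / (S[2] * x2 + S[3]) + dc$U1) / d[1]
  lfy_solve <- function(x3) {
    fixed <- V[4] * x3 / (x3 + S[5]) + V[5] * x3 / (S[6] * x3 + S[7])
    f <- function(x2) {
      x1 <- x1_of(x2)
      d[2] * x2 - (V[3] * x1 / (x1 + S[4]) + fixed)
    }
    if (f(0) >= 0) return(0)
    upper <- (V[3] + fixed + 1) / d[2]
    stats::uniroot(f, c(0, upper), tol = 1e-13)$root
  }
  resid <- function(x3) {
    x2 <- lfy_solve(x3)
    d[3] * x3 - (dc$U2 * V[6] * x2 / (S[8] * x2 + S[9]) +
                   V[7] * x3 / (x3 + S[10]) + V[8] * x3 / (S[11] * x3 + S[12]))
  }
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = grid_size))
  res <- vapply(grid, resid, 0)
  roots <- numeric(0)
  if (abs(resid(0)) < 1e-12) roots <- 0
  idx <- which(diff(sign(res)) != 0)
  for (i in idx) {
    roots <- c(roots, stats::uniroot(resid, c(grid[i], grid[i + 1]), tol = 1e-12)$root)
  }
  lapply(roots, function(r) {
    x2 <- lfy_solve(r)
    st <- stats::setNames(c(x1_of(x2), x2, r), .state_names3)
    rate <- reduced_rhs(0, st, dc, p)
    .steady_state(st, max(abs(rate) / pmax(abs(st), 1)))
  })
}

# Motif cubic ------------------------------------------------------------------

#' Steady-state cubic of the AP1/LFY motif
#'
#' For Hill cooperativity `n = 3` the non-trivial LFY equilibria of the
#' motif satisfy `(omega1 + omega2*F2) x^3 - omega3*F1*F2 x^2 + omega4 = 0`.
#' By Descartes/Vieta this cubic always has one negative root and either two
#' strictly positive roots or a complex pair, so the motif has either zero
#' or two positive steady states; the dichotomy is decided by the sign of
#' the discriminant
#' `Delta3 = omega4 * (4*(omega3*F1*F2)^3 - 27*(omega1 + omega2*F2)^2 * omega4)`.
#'
#' @param mp A `grn_motif` object with `n = 3`.
#' @return Object of class `grn_cubic`: coefficients (descending powers),
#'   `discriminant`, all real roots, `positive_roots` (sorted increasing),
#'   `positive_count` (0 or 2, a double root counted twice), `multiplicity`
#'   tag, the `F1`, `F2` used, and the existence bound `beta4*F1/d2`.
#' @export
motif_cubic <- function(mp) {
  stopifnot(inherits(mp, "grn_motif"))
  if (mp$n != 3) stop("the cubic analysis requires Hill cooperativity n = 3")
  w <- mp$omega
  a <- w[1] + w[2] * mp$F2
  b <- -w[3] * mp$F1 * mp$F2
  disc <- w[4] * (4 * (w[3] * mp$F1 * mp$F2)^3 - 27 * a^2 * w[4])
  rts <- polyroot(c(w[4], 0, b, a))
  real <- sort(Re(rts[abs(Im(rts)) < 1e-8 * max(1, Mod(rts))]))
  double_root <- abs(disc) < 1e-6 * w[4]^2
  if (double_root && length(real) < 3) {
    # at criticality polyroot can report the double root with tiny imaginary
    # parts; recover it from the stationarity condition 3*a*x^2 + 2*b*x = 0
    # and the negative root from the root product -w4/a = neg * dbl^2
    dbl <- -2 * b / (3 * a)
    real <- sort(c(-w[4] / (a * dbl^2), dbl, dbl))
  }
  pos <- real[real > 0]
  bound <- mp$beta4 * mp$F1 / mp$d2
  structure(list(coefficients = c(a, b, 0, w[4]),
                 discriminant = disc,
                 roots = real,
                 positive_roots = pos,
                 positive_count = length(pos),
                 multiplicity = if (double_root) 2L else 1L,
                 F1 = mp$F1, F2 = mp$F2,
                 upper_bound = bound,
                 bound_ok = all(pos < bound)),
            class = "grn_cubic")
}

#' @export
print.grn_cubic <- function(x, ...) {
  cat(sprintf("Motif steady-state cubic at F1 = %g, F2 = %g\n", x$F1, x$F2))
  cat(sprintf("  discriminant %.6g -> %d positive root(s)%s\n", x$discriminant,
              x$positive_count, if (x$multiplicity == 2) " (double)" else ""))
  if (x$positive_count) {
    cat("  positive LFY roots:", paste(signif(x$positive_roots, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Companion steady-state components from an LFY equilibrium
#'
#' Maps a motif LFY equilibrium back to the companion concentrations: AP1 by
#' inverting the LFY balance, `AP1 = d2*LFY*K4 / (beta4*F1 - d2*LFY)` (valid
#' under the existence bound `LFY < beta4*F1/d2`), FD from its explicit
#' equilibrium in LFY, and -- when a SOC1 level is supplied -- AGL24 from its
#' explicit equilibrium in SOC1.
#'
#' @param x2bar LFY equilibrium level (nM).
#' @param mp A `grn_motif` object (supplies `F1`).
#' @param p A `grn_parameters` object (for the FD and AGL24 relations).
#' @param x3bar Optional SOC1 level (nM) for the AGL24 relation.
#' @return Named list with `AP1`, `FD`, and `AGL24` (the latter `NULL`
#'   without `x3bar`).
#' @export
map_equilibrium_relations <- function(x2bar, mp, p = flowering_parameters(),
                                      x3bar = NULL) {
  if (x2bar < 0) stop("LFY level must be non-negative")
  denom <- mp$beta4 * mp$F1 - mp$d2 * x2bar
  if (x2bar > 0 && denom <= 0) {
    stop("LFY level violates the existence bound beta4*F1/d2")
  }
  ap1 <- if (x2bar == 0) 0 else mp$d2 * x2bar * mp$K4 / denom
  fd <- p$beta[10] * hill_activation(x2bar, p$K[13]) / p$d[4]
  agl24 <- if (is.null(x3bar)) NULL else
    p$beta[11] * hill_activation(x3bar, p$K[14]) / p$d[5]
  list(AP1 = ap1, FD = fd, AGL24 = agl24)
}
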