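# Linear stability machinery: analytic Jacobians, characteristic
# coefficients, Routh-Hurwitz predicates, and an eigenvalue/root oracle.
# Because the delayed FT channel is evaluated at its equilibrium value, the
# delay drops out of the linearisation and stability is delay-independent.

# derivative of the Hill activation x^n/(x^n + K^n)
.dhill_act <- function(x, K, n = 1) n * K^n * x^(n - 1) / (x^n + K^n)^2

#' Jacobian of the full model at a state
#'
#' Analytic partial derivatives of the six-gene right-hand side with the
#' delayed FT channel treated as instantaneous (its equilibrium value),
#' which is exact for the stability analysis of a steady state. Row 6 only
#' contains the FT decay `-d6`: the FT equation is autonomous and linear
#' under constant inputs, so `lambda = -d6` is always an eigenvalue and the
#' characteristic polynomial factors as `(lambda + d6) * P(lambda)` with `P`
#' quintic.
#'
#' @param state Length-6 state (nM), typically a steady state.
#' @param p A `grn_parameters` object.
#' @param inputs Constant-mode `grn_inputs`.
#' @return 6x6 numeric matrix (1/min), rows and columns in model order.
#' @export
jacobian_full <- function(state, p, inputs) {
  stopifnot(length(state) == 6)
  b <- p$beta; K <- p$K; d <- p$d; n <- p$n
  x <- as.numeric(state)
  lv <- eval_inputs(inputs, 0)
  kprod <- hill_inhibition(lv[["x7"]], K[11]) * hill_inhibition(lv[["x8"]], K[12])
  J <- matrix(0, 6, 6, dimnames = list(.state_names6, .state_names6))
  J[1, 1] <- -d[1]
  J[1, 2] <- b[1] * .dhill_act(x[2], K[1], n)
  J[1, 4] <- b[2] * .dhill_act(x[4], K[2])
  J[1, 6] <- b[3] * .dhill_act(x[6], K[3])
  J[2, 1] <- b[4] * .dhill_act(x[1], K[4])
  J[2, 2] <- -d[2]
  J[2, 3] <- b[5] * .dhill_act(x[3], K[5])
  J[2, 5] <- b[6] * .dhill_act(x[5], K[6])
  J[3, 3] <- b[7] * .dhill_act(x[3], K[7]) * kprod - d[3]
  J[3, 4] <- b[9] * .dhill_act(x[4], K[9]) * hill_activation(x[6], K[10]) * kprod
  J[3, 5] <- b[8] * .dhill_act(x[5], K[8]) * kprod
  J[3, 6] <- b[9] * hill_activation(x[4], K[9]) * .dhill_act(x[6], K[10]) * kprod
  J[4, 2] <- b[10] * .dhill_act(x[2], K[13])
  J[4, 4] <- -d[4]
  J[5, 3] <- b[11] * .dhill_act(x[3], K[14])
  J[5, 5] <- -d[5]
  J[6, 6] <- -d[6]
  J
}

#' Jacobian of the reduced three-gene model at a state
#'
#' @param state Length-3 state (`AP1, LFY, SOC1`), nM.
#' @param dc A `grn_derived` object.
#' @param p A `grn_parameters` object.
#' @return 3x3 numeric matrix (1/min).
#' @export
jacobian_reduced <- function(state, dc, p) {
  stopifnot(length(state) == 3)
  V <- dc$V; S <- dc$S; d <- p$d
  x <- as.numeric(state)
  # d/dx of V*x/(S_a*x + S_b) = V*S_b/(S_a*x + S_b)^2
  J <- matrix(0, 3, 3, dimnames = list(.state_names3, .state_names3))
  J[1, 1] <- -d[1]
  J[1, 2] <- V[1] * 3 * S[1]^3 * x[2]^2 / (x[2]^3 + S[1]^3)^2 +
    V[2] * S[3] / (S[2] * x[2] + S[3])^2
  J[2, 1] <- V[3] * S[4] / (x[1] + S[4])^2
  J[2, 2] <- -d[2]
  J[2, 3] <- V[4] * S[5] / (x[3] + S[5])^2 + V[5] * S[7] / (S[6] * x[3] + S[7])^2
  J[3, 2] <- dc$U2 * V[6] * S[9] / (S[8] * x[2] + S[9])^2
  J[3, 3] <- V[7] * S[10] / (x[3] + S[10])^2 +
    V[8] * S[12] / (S[11] * x[3] + S[12])^2 - d[3]
  J
}

#' Characteristic polynomial coefficients of a matrix
#'
#' Monic characteristic polynomial `det(lambda*I - J)` computed numerically
#' (Faddeev-LeVerrier), returned as the coefficients of the non-leading
#' terms in descending order, i.e. `(a1, ..., an)` for
#' `lambda^n + a1 lambda^(n-1) + ... + an`.
#'
#' @param J Square numeric matrix.
#' @return Numeric vector of length `nrow(J)`.
#' @export
char_coefficients <- function(J) {
  co <- pracma::charpoly(J)
  co[-1] / co[1]
}

#' Deflate the full-model characteristic polynomial by its FT factor
#'
#' Divides the degree-6 characteristic polynomial by the known linear factor
#' `(lambda + d6)` via synthetic division, returning the quintic
#' coefficients `(a1..a5)` that the Routh-Hurwitz analysis operates on. The
#' division remainder is checked and must be negligible.
#'
#' @param a6 Coefficients `(a1..a6)` of the monic degree-6 polynomial.
#' @param d6 FT degradation rate (1/min).
#' @param tol Remainder tolerance.
#' @return Coefficients `(a1..a5)` of the monic quintic factor.
#' @export
deflate_ft_factor <- function(a6, d6, tol = 1e-9) {
  full <- c(1, a6)
  q <- numeric(6)
  q[1] <- full[1]
  for (i in 2:6) q[i] <- full[i] - d6 * q[i - 1]
  remainder <- full[7] - d6 * q[6]
  scale <- max(abs(full), 1)
  if (abs(remainder) > tol * scale) {
    stop(sprintf("(lambda + d6) is not a factor: remainder %.3g", remainder))
  }
  q[-1]
}

# Routh-Hurwitz predicates -----------------------------------------------------

# classify a margin value: positive (TRUE), negative (FALSE), near-zero (NA)
.rh_margin <- function(value, scale, tol = 1e-9) {
  if (abs(value) <= tol * max(1, scale)) return(NA)
  value > 0
}

#' Routh-Hurwitz test for a monic quintic
#'
#' Necessary and sufficient conditions for all roots of
#' `lambda^5 + a1 lambda^4 + a2 lambda^3 + a3 lambda^2 + a4 lambda + a5`
#' to have negative real parts: `ai > 0` for all `i`,
#' `a1*a2*a3 + a1*a5 > a3^2 + a1^2*a4`, and
#' `(a1*a4 - a5)*(a1*a2*a3 + a1*a5 - a3^2 - a1^2*a4) > a5*(a1*a2 - a3)^2`.
#'
#' @param a Numeric coefficients `(a1..a5)`.
#' @param tol Margin half-width inside which a condition is flagged marginal.
#' @return List with `conditions` (named logical, `NA` = marginal),
#'   `verdict` (`"stable"`, `"unstable"` or `"marginal"`) and the
#'   coefficients.
#' @export
routh_hurwitz_quintic <- function(a, tol = 1e-9) {
  stopifnot(length(a) == 5)
  h1 <- a[1] * a[2] * a[3] + a[1] * a[5] - a[3]^2 - a[1]^2 * a[4]
  h2 <- (a[1] * a[4] - a[5]) * h1 - a[5] * (a[1] * a[2] - a[3])^2
  sc <- max(abs(a), 1)
  conds <- c(
    stats::setNames(lapply(seq_along(a), function(i) .rh_margin(a[i], sc, tol)),
                    paste0("a", 1:5, "_positive")),
    list(hurwitz_2 = .rh_margin(h1, sc^3, tol),
         hurwitz_3 = .rh_margin(h2, sc^5, tol))
  )
  conds <- unlist(conds)
  verdict <- if (any(is.na(conds))) "marginal" else
    if (all(conds)) "stable" else "unstable"
  list(coefficients = a, conditions = conds, verdict = verdict)
}

#' Routh-Hurwitz test for a monic cubic
#'
#' All roots of `lambda^3 + a1 lambda^2 + a2 lambda + a3` have negative
#' real parts iff `a1, a2, a3 > 0` and `a1*a2 > a3`.
#'
#' @param a Numeric coefficients `(a1..a3)`.
#' @param tol Margin half-width for the marginal band.
#' @return List with `conditions`, `verdict` and the coefficients.
#' @export
routh_hurwitz_cubic <- function(a, tol = 1e-9) {
  stopifnot(length(a) == 3)
  sc <- max(abs(a), 1)
  conds <- c(
    stats::setNames(lapply(1:3, function(i) .rh_margin(a[i], sc, tol)),
                    paste0("a", 1:3, "_positive")),
    list(hurwitz_2 = .rh_margin(a[1] * a[2] - a[3], sc^2, tol))
  )
  conds <- unlist(conds)
  verdict <- if (any(is.na(conds))) "marginal" else
    if (all(conds)) "stable" else "unstable"
  list(coefficients = a, conditions = conds, verdict = verdict)
}

#' Stability of a motif equilibrium
#'
#' For a positive LFY equilibrium of the two-gene motif the 2x2 Jacobian is
#' Hurwitz iff `x2bar^(n-1) > n*d1*d2*K1^n*K4 / (beta1*beta4*F1*F2)`;
#' equality marks the saddle-node (double-root) degeneracy. The trivial
#' state `(0, 0)` is always stable (eigenvalues `-d1`, `-d2`).
#'
#' @param x2bar LFY equilibrium (nM), a root of the motif cubic (or 0).
#' @param mp A `grn_motif` object.
#' @param tol Relative band inside which the condition counts as marginal.
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @export
motif_stability <- function(x2bar, mp, tol = 1e-9) {
  if (x2bar < 0) stop("LFY equilibrium must be non-negative")
  if (x2bar == 0) return("stable")
  if (mp$d2 * x2bar >= mp$beta4 * mp$F1) {
    stop("LFY equilibrium violates the existence bound beta4*F1/d2")
  }
  thr <- mp$n * mp$d1 * mp$d2 * mp$K1^mp$n * mp$K4 /
    (mp$beta1 * mp$beta4 * mp$F1 * mp$F2)
  lhs <- x2bar^(mp$n - 1)
  if (abs(lhs - thr) <= tol * max(1, thr)) return("marginal")
  if (lhs > thr) "stable" else "unstable"
}

#' Jacobian of the two-gene motif
#'
#' @param state Length-2 state (`AP1, LFY`), nM.
#' @param mp A `grn_motif` object.
#' @return 2x2 numeric matrix (1/min).
#' @export
motif_jacobian <- function(state, mp) {
  x <- as.numeric(state)
  matrix(c(-mp$d1,
           mp$beta4 * mp$K4 * mp$F1 / (x[1] + mp$K4)^2,
           mp$n * mp$beta1 * mp$K1^mp$n * mp$F2 * x[2]^(mp$n - 1) /
             (x[2]^mp$n + mp$K1^mp$n)^2,
           -mp$d2),
         2, 2, dimnames = list(c("AP1", "LFY"), c("AP1", "LFY")))
}

#' Full stability report for a steady state
#'
#' Builds the Jacobian, extracts the characteristic coefficients, deflates
#' the known FT factor, evaluates the Routh-Hurwitz conditions and compares
#' the verdict with an eigenvalue oracle.
#'
#' @param ss A `grn_steady_state` (full model) or a length-6 state vector.
#' @param p A `grn_parameters` object.
#' @param inputs Constant-mode `grn_inputs`.
#' @param tol Marginal band for the predicates.
#' @return Object of class `grn_stability`: steady state, quintic
#'   coefficients, condition truth values, eigenvalues, verdict, and the
#'   eigenvalue-oracle verdict.
#' @export
stability_report <- function(ss, p, inputs, tol = 1e-9) {
  state <- if (inherits(ss, "grn_steady_state")) ss$state else ss
  J <- jacobian_full(state, p, inputs)
  a6 <- char_coefficients(J)
  a5 <- deflate_ft_factor(a6, p$d[6])
  rh <- routh_hurwitz_quintic(a5, tol)
  ev <- eigen(J, only.values = TRUE)$values
  mx <- max(Re(ev))
  oracle <- if (abs(mx) <= tol) "marginal" else if (mx < 0) "stable" else "unstable"
  structure(list(state = state, jacobian = J,
                 quintic = a5, conditions = rh$conditions,
                 eigenvalues = ev, verdict = rh$verdict,
                 eigen_verdict = oracle),
            class = "grn_stability")
}

#' @export
print.grn_stability <- function(x, ...) {
  cat("Stability report (full model steady state)\n")
  cat("  quintic coefficients:", paste(signif(x$quintic, 6), collapse = " "), "\n")
  cat("  Routh-Hurwitz verdict:", x$verdict,
      " | eigenvalue oracle:", x$eigen_verdict, "\n")
  cat("  max Re(lambda):", signif(max(Re(x$eigenvalues)), 6), "per min\n")
  invisible(x)
}
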