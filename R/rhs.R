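# Model right-hand sides. State ordering is fixed throughout the package:
# x1 = AP1, x2 = LFY, x3 = SOC1, x4 = FD, x5 = AGL24, x6 = FT (nM), time in
# minutes. The FT channel is produced in the leaves and acts on AP1 and SOC1
# after a transport delay, so those two equations read a delayed FT value.

.state_names6 <- c("AP1", "LFY", "SOC1", "FD", "AGL24", "FT")
.state_names3 <- c("AP1", "LFY", "SOC1")

#' Full six-gene model right-hand side
#'
#' Rates of change of the six internal concentrations. The delayed FT value
#' enters the AP1 equation (direct activation) and the SOC1 equation (joint
#' FT-FD activation); the instantaneous FT only decays and is produced under
#' SVP/FLC repression in the leaves.
#'
#' @param t Time (min), used to evaluate time-varying inputs.
#' @param x State vector of length 6 (`AP1, LFY, SOC1, FD, AGL24, FT`), nM.
#' @param x6_delayed Delayed FT concentration `x6(t - delta)`, nM.
#' @param p A `grn_parameters` object.
#' @param inputs A `grn_inputs` object.
#' @return Numeric length-6 vector of rates (nM/min).
#' @export
full_rhs <- function(t, x, x6_delayed, p, inputs) {
  if (length(x) != 6) stop("full model state must have 6 components")
  if (x6_delayed < 0) stop("delayed FT concentration must be non-negative")
  b <- p$beta; K <- p$K; d <- p$d; n <- p$n
  iv <- eval_inputs(inputs, t)
  c(
    b[1] * hill_activation(x[2], K[1], n) + b[2] * hill_activation(x[4], K[2]) +
      b[3] * hill_activation(x6_delayed, K[3]) - d[1] * x[1],
    b[4] * hill_activation(x[1], K[4]) + b[5] * hill_activation(x[3], K[5]) +
      b[6] * hill_activation(x[5], K[6]) - d[2] * x[2],
    (b[7] * hill_activation(x[3], K[7]) + b[8] * hill_activation(x[5], K[8]) +
       b[9] * hill_activation(x[4], K[9]) * hill_activation(x6_delayed, K[10])) *
      hill_inhibition(iv[["x7"]], K[11]) * hill_inhibition(iv[["x8"]], K[12]) -
      d[3] * x[3],
    b[10] * hill_activation(x[2], K[13]) - d[4] * x[4],
    b[11] * hill_activation(x[3], K[14]) - d[5] * x[5],
    b[12] * hill_inhibition(iv[["x9"]], K[15]) * hill_inhibition(iv[["x10"]], K[16]) -
      d[6] * x[6]
  )
}

#' Reduced three-gene model right-hand side
#'
#' Rates for the AP1/LFY/SOC1 system obtained by assuming FD, AGL24 and FT
#' equilibrate instantaneously, expressed through the derived constants
#' `V`, `S`, `U1`, `U2`.
#'
#' @param t Time (min); unused (the reduced model is autonomous) but kept
#'   for a uniform integrator interface.
#' @param x State vector of length 3 (`AP1, LFY, SOC1`), nM.
#' @param dc A `grn_derived` object.
#' @param p A `grn_parameters` object (degradation rates `d1..d3`).
#' @return Numeric length-3 vector of rates (nM/min).
#' @export
reduced_rhs <- function(t, x, dc, p) {
  if (length(x) != 3) stop("reduced model state must have 3 components")
  V <- dc$V; S <- dc$S; d <- p$d
  c(
    V[1] * x[2]^3 / (x[2]^3 + S[1]^3) + V[2] * x[2] / (S[2] * x[2] + S[3]) +
      dc$U1 - d[1] * x[1],
    V[3] * x[1] / (x[1] + S[4]) + V[4] * x[3] / (x[3] + S[5]) +
      V[5] * x[3] / (S[6] * x[3] + S[7]) - d[2] * x[2],
    dc$U2 * V[6] * x[2] / (S[8] * x[2] + S[9]) + V[7] * x[3] / (x[3] + S[10]) +
      V[8] * x[3] / (S[11] * x[3] + S[12]) - d[3] * x[3]
  )
}

#' Two-gene AP1/LFY motif right-hand side
#'
#' Mutual activation of AP1 and LFY with external FT / FT-FD action factors:
#' `dAP1/dt = beta1 * F2 * LFY^n/(LFY^n + K1^n) - d1 * AP1`,
#' `dLFY/dt = beta4 * F1 * AP1/(AP1 + K4) - d2 * LFY`.
#'
#' @param t Time (min); unused, kept for interface uniformity.
#' @param x State vector of length 2 (`AP1, LFY`), nM.
#' @param mp A `grn_motif` object.
#' @return Numeric length-2 vector of rates (nM/min).
#' @export
motif_rhs <- function(t, x, mp) {
  if (length(x) != 2) stop("motif state must have 2 components")
  c(
    mp$beta1 * mp$F2 * hill_activation(x[2], mp$K1, mp$n) - mp$d1 * x[1],
    mp$beta4 * mp$F1 * hill_activation(x[1], mp$K4) - mp$d2 * x[2]
  )
}
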