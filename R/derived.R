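#' Derived constants of the reduced three-gene model
#'
#' Collapses the fast/decoupled variables (FD, AGL24, FT) into the effective
#' rates `V1..V8`, saturation constants `S1..S12` and input-effect constants
#' `u`, `U1`, `U2` of the reduced AP1/LFY/SOC1 system. Requires constant
#' external inputs: `u` is the resulting constant FT level, `U1` the FT
#' drive on AP1 and `U2` the FT-FD occupancy factor acting on SOC1.
#'
#' @param p A `grn_parameters` object.
#' @param inputs A `grn_inputs` object in constant mode.
#' @return Object of class `grn_derived`: list with `u`, `U1`, `U2`,
#'   numeric vectors `V` (8) and `S` (12), and the inhibition factors
#'   `kappa11`, `kappa12` evaluated at the input levels.
#' @examples
#' dc <- derive_constants(flowering_parameters(), default_input_levels())
#' dc$V[2]   # beta2 * beta10
#' @export
derive_constants <- function(p, inputs) {
  stopifnot(inherits(p, "grn_parameters"))
  if (!inherits(inputs, "grn_inputs") || inputs$mode != "constant") {
    stop("derive_constants requires inputs in constant mode")
  }
  b <- p$beta; K <- p$K; d <- p$d
  lv <- inputs$levels
  k11 <- hill_inhibition(lv[["x7"]], K[11])
  k12 <- hill_inhibition(lv[["x8"]], K[12])
  k15 <- hill_inhibition(lv[["x9"]], K[15])
  k16 <- hill_inhibition(lv[["x10"]], K[16])
  u <- b[12] * k15 * k16 / d[6]
  V <- c(b[1], b[2] * b[10], b[4], b[5], b[6] * b[11],
         b[9] * b[10] * k11 * k12, b[7] * k11 * k12, b[8] * b[11] * k11 * k12)
  S <- c(K[1], b[10] + d[4] * K[2], d[4] * K[2] * K[13],
         K[4], K[5], b[11] + d[5] * K[6], d[5] * K[6] * K[14],
         b[10] + d[4] * K[9], d[4] * K[9] * K[13],
         K[7], b[11] + d[5] * K[8], d[5] * K[8] * K[14])
  structure(list(u = u,
                 U1 = b[3] * u / (u + K[3]),
                 U2 = u / (u + K[10]),
                 V = V, S = S,
                 kappa11 = k11, kappa12 = k12), class = "grn_derived")
}

#' Two-gene motif parameters
#'
#' Parameter block for the AP1/LFY motif: the mutual-activation constants
#' inherited from the full model plus the external FT-FD / FT action factors
#' `F1` (on LFY) and `F2` (on AP1), which inhibit for `F < 1` and activate
#' for `F > 1`. Also carries the four cubic coefficients
#' `omega1 = d1*d2*K4`, `omega2 = d2*beta1`, `omega3 = beta1*beta4`,
#' `omega4 = d1*d2*K1^n*K4` used by the steady-state polynomial.
#'
#' @param p A `grn_parameters` object supplying `beta1`, `beta4`, `K1`,
#'   `K4`, `d1`, `d2` and `n`.
#' @param F1,F2 Positive action factors of FT-FD on LFY and FT on AP1.
#' @return Object of class `grn_motif`.
#' @export
motif_params <- function(p = flowering_parameters(), F1 = 1, F2 = 1) {
  stopifnot(inherits(p, "grn_parameters"))
  if (!is.finite(F1) || !is.finite(F2) || F1 <= 0 || F2 <= 0) {
    stop("F1 and F2 must be positive")
  }
  mp <- list(beta1 = p$beta[1], beta4 = p$beta[4],
             K1 = p$K[1], K4 = p$K[4],
             d1 = p$d[1], d2 = p$d[2], n = p$n,
             F1 = F1, F2 = F2)
  mp$omega <- c(mp$d1 * mp$d2 * mp$K4,
                mp$d2 * mp$beta1,
                mp$beta1 * mp$beta4,
                mp$d1 * mp$d2 * mp$K1^mp$n * mp$K4)
  structure(mp, class = "grn_motif")
}

#' @export
print.grn_motif <- function(x, ...) {
  cat(sprintf("AP1/LFY motif: F1 = %g, F2 = %g, n = %d\n", x$F1, x$F2, x$n))
  cat("  omega:", paste(signif(x$omega, 6), collapse = " "), "\n")
  invisible(x)
}
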