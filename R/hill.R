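#' Hill activation kinetics
#'
#' Saturating activation `x^n / (x^n + K^n)`, the building block of every
#' transcription term in the flowering network. `n = 1` gives
#' Michaelis-Menten-type activation; `n > 1` models cooperative binding
#' (the LFY -> AP1 edge uses `n = 3`).
#'
#' @param x Activator concentration (nM), scalar or vector, `>= 0`.
#' @param K Half-maximal abundance (nM), `> 0`.
#' @param n Hill cooperativity, integer `>= 1`.
#' @return Fraction of maximal transcription in `[0, 1)`; strictly
#'   increasing in `x`, equal to 1/2 at `x = K`.
#' @examples
#' hill_activation(452.395, 7.9)         # near saturation
#' hill_activation(9.82, 9.82, n = 3)    # half-maximal
#' @export
hill_activation <- function(x, K, n = 1L) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("hill_activation: concentration 'x' must be finite and non-negative")
  }
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("hill_activation: half-max constant 'K' must be finite and positive")
  }
  if (any(n < 1) || any(n != round(n))) {
    stop("hill_activation: Hill exponent 'n' must be a positive integer")
  }
  xn <- x^n
  xn / (xn + K^n)
}

#' Hill inhibition kinetics
#'
#' Saturating repression `K / (x + K)`: full transcription with no
#' inhibitor, half-maximal at `x = K`, vanishing as `x` grows. Used for the
#' SVP/FLC repression of SOC1 and FT.
#'
#' @param x Inhibitor concentration (nM), scalar or vector, `>= 0`.
#' @param K Half-maximal abundance (nM), `> 0`.
#' @return Fraction of maximal transcription in `(0, 1]`, strictly
#'   decreasing in `x`.
#' @export
hill_inhibition <- function(x, K) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("hill_inhibition: concentration 'x' must be finite and non-negative")
  }
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("hill_inhibition: half-max constant 'K' must be finite and positive")
  }
  K / (x + K)
}
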