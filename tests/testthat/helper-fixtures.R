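# Shared fixtures: the published constants, calibrated inputs, and the
# best-match motif. All built in code at test time.

fix_params <- function(...) flowering_parameters(...)
fix_inputs <- function() default_input_levels()
fix_motif <- function(F1 = 1.3445, F2 = 1.0476) motif_params(fix_params(), F1, F2)

# published positive steady state of the full network (nM)
table3_state <- function() {
  c(AP1 = 121.567, LFY = 452.395, SOC1 = 827.835, FD = 1113.882,
    AGL24 = 86881.258, FT = 2.037)
}

# coefficients (a1..an) of the monic polynomial with the given roots
coeffs_from_roots <- function(roots) {
  co <- 1
  for (r in roots) co <- c(co, 0) - c(0, r * co)
  Re(co[-1])
}

# sign of the largest real part of the roots of the monic polynomial
# lambda^n + a1 lambda^(n-1) + ... + an  (independent root oracle)
max_re_root <- function(a) {
  max(Re(polyroot(rev(c(1, a)))))
}
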