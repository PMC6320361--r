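test_that("quintic Routh-Hurwitz verdicts match known polynomials", {
  # (lambda + 1)^5: all roots at -1
  expect_identical(routh_hurwitz_quintic(c(5, 10, 10, 5, 1))$verdict, "stable")
  # (lambda + 1)^4 (lambda - 0.1): one unstable root
  a <- coeffs_from_roots(c(-1, -1, -1, -1, 0.1))
  expect_equal(a, c(3.9, 5.6, 3.4, 0.6, -0.1))
  rh <- routh_hurwitz_quintic(a)
  expect_identical(rh$verdict, "unstable")
  expect_true(any(!rh$conditions, na.rm = TRUE))
  expect_gt(max_re_root(a), 0)
})

test_that("cubic Routh-Hurwitz verdicts match known polynomials", {
  expect_identical(routh_hurwitz_cubic(c(3, 3, 1))$verdict, "stable")
  rh <- routh_hurwitz_cubic(c(1, 1, 2))     # a1 a2 < a3
  expect_identical(rh$verdict, "unstable")
  expect_gt(max_re_root(c(1, 1, 2)), 0)
  expect_identical(routh_hurwitz_cubic(c(2, 1, 0))$verdict, "marginal")
})

test_that("predicates agree with the root oracle on random polynomials", {
  set.seed(31)
  n_quintic <- 0; n_cubic <- 0
  while (n_quintic < 700 || n_cubic < 300) {
    if (n_quintic < 700) {
      a <- runif(5, -3, 3)
      mx <- max_re_root(a)
      if (abs(mx) > 1e-9) {
        v <- routh_hurwitz_quintic(a)$verdict
        expect_identical(v, if (mx < 0) "stable" else "unstable")
        n_quintic <- n_quintic + 1
      }
    }
    if (n_cubic < 300) {
      a <- runif(3, -3, 3)
      mx <- max_re_root(a)
      if (abs(mx) > 1e-9) {
        v <- routh_hurwitz_cubic(a)$verdict
        expect_identical(v, if (mx < 0) "stable" else "unstable")
        n_cubic <- n_cubic + 1
      }
    }
  }
})

test_that("the full-model Jacobian has the analytic structure and values", {
  p <- fix_params(); inp <- fix_inputs()
  ss <- solve_full_steady_state(p, inp)[[1]]$state
  J <- jacobian_full(ss, p, inp)
  # FT equation is autonomous and linear
  expect_equal(unname(J[6, ]), c(0, 0, 0, 0, 0, -0.1))
  # central-difference oracle
  h <- 1e-4
  Jfd <- matrix(0, 6, 6)
  for (j in 1:6) {
    e <- rep(0, 6); e[j] <- h * max(ss[j], 1)
    Jfd[, j] <- (full_rhs(0, ss + e, (ss + e)[6], p, inp) -
                   full_rhs(0, ss - e, (ss - e)[6], p, inp)) / (2 * e[j])
  }
  expect_equal(unname(J), Jfd, tolerance = 1e-6)
  # lambda = -d6 is always an eigenvalue; deflation leaves no remainder
  a6 <- char_coefficients(J)
  a5 <- deflate_ft_factor(a6, p$d[6])
  expect_length(a5, 5)
  # deflated quintic times (lambda + d6) reproduces the sextic
  rebuilt <- c(1, a5) * 1
  full <- c(rebuilt, 0) + p$d[6] * c(0, rebuilt)
  expect_equal(full[-1], a6, tolerance = 1e-9)
})

test_that("the published steady state is stable by both predicate and oracle", {
  p <- fix_params(); inp <- fix_inputs()
  ss <- solve_full_steady_state(p, inp)[[1]]
  rep <- stability_report(ss, p, inp)
  expect_identical(rep$verdict, "stable")
  expect_identical(rep$eigen_verdict, "stable")
  expect_lt(max(Re(rep$eigenvalues)), 0)
})

test_that("reduced-model stability agrees between cubic predicate and eigenvalues", {
  p <- fix_params(); inp <- fix_inputs()
  dc <- derive_constants(p, inp)
  ss <- solve_reduced_steady_state(p, dc)[[1]]$state
  J <- jacobian_reduced(ss, dc, p)
  a3 <- char_coefficients(J)
  expect_identical(routh_hurwitz_cubic(a3)$verdict, "stable")
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
})

test_that("motif equilibria are classified as the phase portrait dictates", {
  mp <- fix_motif()
  cb <- motif_cubic(mp)
  expect_identical(motif_stability(cb$positive_roots[2], mp), "stable")
  expect_identical(motif_stability(cb$positive_roots[1], mp), "unstable")
  expect_identical(motif_stability(0, mp), "stable")
  # verdicts agree with the 2x2 Jacobian eigenvalues
  for (i in 1:2) {
    x2 <- cb$positive_roots[i]
    x1 <- map_equilibrium_relations(x2, mp)$AP1
    mx <- max(Re(eigen(motif_jacobian(c(x1, x2), mp))$values))
    expect_identical(motif_stability(x2, mp),
                     if (mx < 0) "stable" else "unstable")
  }
  expect_error(motif_stability(1e9, mp), "bound")
})

test_that("the stability margin vanishes exactly at the saddle-node", {
  p <- fix_params()
  bf <- find_critical_F("subsystem1", p)
  mp <- motif_params(p, 1, bf$F_critical)
  x2 <- bf$lfy_double_root
  thr <- mp$n * mp$d1 * mp$d2 * mp$K1^mp$n * mp$K4 /
    (mp$beta1 * mp$beta4 * mp$F1 * mp$F2)
  expect_equal(x2^(mp$n - 1) / thr, 1, tolerance = 1e-4)
  expect_identical(motif_stability(x2, mp, tol = 1e-4), "marginal")
})
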