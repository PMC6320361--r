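test_that("Hill activation matches its defining values and rejects bad input", {
  expect_identical(hill_activation(0, 9.82, 3), 0)
  expect_equal(hill_activation(9.82, 9.82, 3), 0.5)
  expect_equal(hill_activation(123.4, 123.4, 1), 0.5)
  # value used in the FD equilibrium relation, frozen from direct evaluation
  expect_equal(hill_activation(452.395, 7.9, 1), 0.98284, tolerance = 1e-5)
  expect_error(hill_activation(-1, 5), "non-negative")
  expect_error(hill_activation(1, 0), "positive")
  expect_error(hill_activation(1, 5, n = 0), "positive integer")
})

test_that("Hill inhibition matches its defining values and saturates", {
  expect_identical(hill_inhibition(0, 909), 1)
  expect_equal(hill_inhibition(501, 501), 0.5)
  expect_lt(hill_inhibition(1e12, 501), 1e-9)
  expect_error(hill_inhibition(-0.1, 5), "non-negative")
  expect_error(hill_inhibition(1, -5), "positive")
})

test_that("activation and inhibition with n = 1 are complementary and monotone", {
  set.seed(101)
  for (i in 1:50) {
    K <- exp(runif(1, log(1e-3), log(2e3)))
    x <- sort(exp(runif(20, log(1e-4), log(1e5))))
    expect_equal(hill_activation(x, K) + hill_inhibition(x, K), rep(1, 20))
    # monotone; strictly so until floating-point saturation at 1
    act <- hill_activation(x, K, 3)
    expect_true(all(diff(act) >= 0))
    expect_true(all(diff(act)[act[-20] < 1 - 1e-9] > 0))
    expect_true(all(diff(hill_inhibition(x, K)) < 0))
  }
})

test_that("the parameter registry carries the printed constants and units", {
  p <- fix_params()
  expect_equal(p$beta[c(1, 4, 12)], c(99.8, 22, 51))
  expect_equal(p$K[c(1, 4, 16)], c(9.82, 346, 985))
  expect_equal(p$d, c(0.86, 0.017, 0.11, 0.0075, 0.001, 0.1))
  expect_identical(p$n, 3L)
  expect_equal(p$delta_days, 0.5)
  expect_equal(p$delta_min, 720)     # day -> minute conversion at the boundary
})

test_that("overrides, config files and validation behave", {
  expect_equal(fix_params(list(beta4 = 30))$beta[4], 30)
  expect_error(fix_params(list(gamma1 = 2)), "unknown parameter")
  expect_error(fix_params(list(beta1 = 300)), "range")
  expect_error(fix_params(list(d2 = -0.1)), "positive")
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(K4 = 350), cfg, auto_unbox = TRUE)
  expect_equal(fix_params(file = cfg)$K[4], 350)
  r <- parameter_ranges()
  expect_equal(r$beta, c(0.001, 200))
  expect_equal(r$K, c(0.001, 2000))
  expect_equal(r$d, c(0.001, 1))
})

test_that("input signal containers evaluate correctly in both modes", {
  ci <- constant_inputs(1, 2, 3, 4)
  expect_equal(eval_inputs(ci, 0), eval_inputs(ci, 1e6))
  expect_error(constant_inputs(-1, 2, 3, 4), "non-negative")
  pw <- piecewise_inputs(c(0, 100), rbind(c(0, 1, 2, 3), c(10, 1, 2, 3)))
  expect_equal(unname(eval_inputs(pw, 50)[["x7"]]), 5)
  expect_equal(unname(eval_inputs(pw, 1e5)[["x7"]]), 10)  # held at boundary
  expect_error(piecewise_inputs(c(0, 100), rbind(c(0, 1, -2, 3), c(1, 1, 2, 3))),
               "non-negative")
})

test_that("derived constants reproduce their defining products exactly", {
  p <- fix_params()
  dc <- derive_constants(p, fix_inputs())
  expect_equal(dc$V[2], 42.5)          # beta2 * beta10 = 5 * 8.5
  expect_equal(dc$S[3], 41.475)        # d4 * K2 * K13 = 0.0075 * 700 * 7.9
  expect_equal(dc$V[1], p$beta[1])
  expect_equal(dc$S[6], p$beta[11] + p$d[5] * p$K[6])
  # u satisfies its defining balance
  lv <- fix_inputs()$levels
  u_expect <- p$beta[12] * hill_inhibition(lv[["x9"]], p$K[15]) *
    hill_inhibition(lv[["x10"]], p$K[16]) / p$d[6]
  expect_equal(dc$u, u_expect)
  # zero FT transcription kills the FT drive on AP1
  p0 <- fix_params(list(beta3 = 0.001))
  expect_equal(derive_constants(p0, fix_inputs())$U1,
               0.001 * dc$u / (dc$u + p$K[3]))
  # pure arithmetic: repeated calls agree exactly
  expect_identical(dc, derive_constants(p, fix_inputs()))
  # constant-mode precondition
  pw <- piecewise_inputs(c(0, 10), rbind(c(1, 1, 1, 1), c(2, 2, 2, 2)))
  expect_error(derive_constants(p, pw), "constant mode")
})

test_that("the calibrated input levels reproduce the published FT level", {
  dc <- derive_constants(fix_params(), fix_inputs())
  expect_equal(dc$u, table3_state()[["FT"]], tolerance = 1e-10)
})
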