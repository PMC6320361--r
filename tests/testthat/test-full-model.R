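test_that("the right-hand side vanishes at the solved steady state", {
  p <- fix_params(); inp <- fix_inputs()
  ss <- solve_full_steady_state(p, inp)[[1]]$state
  rate <- full_rhs(0, ss, ss[["FT"]], p, inp)
  expect_lt(max(abs(rate) / pmax(abs(ss), 1)), 1e-9)
})

test_that("rates at the origin are pure production, and pure decay without transcription", {
  p <- fix_params(); inp <- fix_inputs()
  # at the origin all activation-driven production vanishes; only the
  # constitutive (repression-gated) FT production remains
  r0 <- full_rhs(0, rep(0, 6), 0, p, inp)
  expect_true(all(r0 >= 0))
  expect_gt(r0[6], 0)
  p0 <- fix_params(lapply(stats::setNames(rep(0.001, 12), paste0("beta", 1:12)),
                          identity))
  x <- c(10, 20, 30, 40, 50, 60)
  rate <- full_rhs(0, x, x[6], p0, inp)
  # production bounded by the tiny beta floor; decay dominates
  expect_true(all(rate < 0))
  # |production| bounded by the sum of (at most three) beta-floor terms
  expect_true(all(abs(rate + p0$d * x) < 0.0035))
  expect_error(full_rhs(0, rep(1, 5), 1, p, inp), "6 components")
})

test_that("the fast integrator right-hand side agrees with the reference one", {
  p <- fix_params(); inp <- fix_inputs()
  f <- floradyn:::.full_rhs_fast(p, inp)
  set.seed(7)
  for (i in 1:20) {
    y <- exp(runif(6, log(1e-3), log(1e4)))
    ylag <- y * runif(6, 0.5, 2)
    expect_equal(f(0, y, ylag), full_rhs(0, y, ylag[6], p, inp))
  }
})

test_that("method of steps solves the scalar delayed decay test problem", {
  # y' = -y(t - 1), constant history 1: y(t) = 1 - t on [0, 1]
  tr <- integrate_dde(function(t, y, ylag) -ylag, 1, delta = 1, horizon = 1,
                      step = 0.05)
  expect_equal(tr$y1, 1 - tr$time_min, tolerance = 1e-12)
  expect_error(integrate_dde(function(t, y, ylag) -ylag, 1, delta = 1,
                             horizon = 1, step = 2), "exceed the delay")
})

test_that("zero delay reduces exactly to an ODE and matches deSolve", {
  p <- fix_params(); inp <- fix_inputs()
  mine <- simulate_full(p, inp, horizon_days = 1, step_min = 1, delta_min = 0)
  ref <- deSolve::ode(y = unname(germination_state()),
                      times = c(0, 1440),
                      func = function(t, y, parms)
                        list(full_rhs(t, y, y[6], p, inp)),
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  endp <- unlist(mine[nrow(mine), -(1:2)])
  expect_equal(unname(endp), unname(ref[2, -1]), tolerance = 1e-6)
})

test_that("the delayed integration agrees with an adaptive DDE oracle", {
  p <- fix_params(); inp <- fix_inputs()
  y0 <- germination_state()
  oracle <- deSolve::dede(y = unname(y0), times = c(0, 2880),
                          func = function(t, y, parms) {
                            ylag <- if (t < 720) y0 else deSolve::lagvalue(t - 720)
                            list(full_rhs(t, y, ylag[6], p, inp))
                          }, parms = NULL, rtol = 1e-10, atol = 1e-10)
  mine <- simulate_full(p, inp, horizon_days = 2, step_min = 1)
  endp <- unlist(mine[nrow(mine), -(1:2)])
  expect_equal(unname(endp), unname(oracle[2, -1]), tolerance = 1e-5)
})

test_that("halving the step shows at least fourth-order endpoint convergence", {
  p <- fix_params(); inp <- fix_inputs()
  endpoint <- function(step) {
    tr <- simulate_full(p, inp, horizon_days = 0.5, step_min = step)
    unlist(tr[nrow(tr), -(1:2)])
  }
  e1 <- endpoint(2); e2 <- endpoint(1); e3 <- endpoint(0.5)
  err1 <- max(abs(e1 - e3)); err2 <- max(abs(e2 - e3))
  # RK4 within segments: halving the step should cut the error by ~2^4;
  # require at least a factor 8 to allow interpolation-order pollution
  expect_gt(err1 / err2, 8)
})

test_that("trajectories from non-negative states stay non-negative", {
  p <- fix_params(); inp <- fix_inputs()
  set.seed(11)
  for (i in 1:3) {
    init <- runif(6, 0, 50)
    tr <- simulate_full(p, inp, init = init, horizon_days = 2, step_min = 1)
    expect_true(all(as.matrix(tr[, -(1:2)]) >= -1e-12))
  }
})

test_that("the endpoint steady state is invariant to the transport delay", {
  p <- fix_params(); inp <- fix_inputs()
  with_delay <- simulate_full(p, inp, horizon_days = 40, step_min = 2)
  no_delay <- simulate_full(p, inp, horizon_days = 40, step_min = 2,
                            delta_min = 0)
  a <- unlist(with_delay[nrow(with_delay), -(1:2)])
  b <- unlist(no_delay[nrow(no_delay), -(1:2)])
  expect_lt(max(abs(a - b) / abs(b)), 0.001)
})

test_that("the divergence guard names the failure time", {
  expect_error(integrate_dde(function(t, y, ylag) 10 * y, 1, delta = 0,
                             horizon = 10, step = 0.5, guard = 100),
               "diverged at t")
})

test_that("reduced model rates match the printed structure", {
  p <- fix_params(); dc <- derive_constants(p, fix_inputs())
  r0 <- reduced_rhs(0, c(0, 0, 0), dc, p)
  expect_equal(r0, c(dc$U1, 0, 0))
  ss <- solve_reduced_steady_state(p, dc)[[1]]$state
  expect_lt(max(abs(reduced_rhs(0, ss, dc, p))), 1e-8)
  expect_error(reduced_rhs(0, c(1, 2), dc, p), "3 components")
})

test_that("the reduced model tracks the full model's AP1 behaviour", {
  p <- fix_params(); inp <- fix_inputs()
  full_ss <- solve_full_steady_state(p, inp)[[1]]$state
  red_ss <- solve_reduced_steady_state(p, inp)[[1]]$state
  # decoupling preserves the attractor of the retained variables
  expect_equal(unname(red_ss), unname(full_ss[1:3]), tolerance = 1e-6)
  init <- germination_state()[c("AP1", "LFY", "SOC1")]
  tr <- simulate_reduced(p, inp, init, horizon_days = 30, step_min = 10)
  expect_equal(tr$AP1[nrow(tr)], full_ss[["AP1"]], tolerance = 1e-3)
})
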