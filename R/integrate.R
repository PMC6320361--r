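# Trajectory container -------------------------------------------------------

.make_trajectory <- function(times_min, states, model, step = NA_real_,
                             delta_min = NA_real_) {
  states <- as.matrix(states)
  stopifnot(nrow(states) == length(times_min))
  df <- data.frame(time_min = times_min, day = times_min / 1440, states,
                   check.names = FALSE)
  structure(df, class = c("grn_trajectory", "data.frame"),
            model = model, step_min = step, delta_min = delta_min)
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of the %s model: %d points on [0, %.4g] days\n",
              attr(x, "model"), nrow(x), max(x$day)))
  vars <- setdiff(names(x), c("time_min", "day"))
  final <- vapply(vars, function(v) x[[v]][nrow(x)], 0)
  cat("  final state:", paste(sprintf("%s=%.6g", vars, final), collapse = ", "), "\n")
  invisible(x)
}

# DDE integrator --------------------------------------------------------------

#' Integrate a delay differential equation by the method of steps
#'
#' Fixed-step classical Runge-Kutta integration of `y' = rhs(t, y, y(t -
#' delta))` with a constant history equal to the initial state on
#' `[-delta, 0]`. The delayed state is read from the stored trajectory by
#' linear interpolation; because the step never exceeds the delay, every
#' lagged lookup falls in the already-computed past, so each RK4 segment is
#' an ordinary ODE step. With `delta = 0` the lagged argument is the current
#' stage state and the scheme reduces exactly to classical RK4 for an ODE.
#'
#' @param rhs Function `rhs(t, y, ylag)` returning the rate vector; `ylag`
#'   is the full state vector at `t - delta`.
#' @param y0 Initial (and history) state vector.
#' @param delta Delay (min), `>= 0`.
#' @param horizon Integration horizon (min), `> 0`.
#' @param step Step size (min); must not exceed `delta` unless `delta = 0`.
#' @param var_names Optional column names for the state.
#' @param model Tag stored on the returned trajectory.
#' @param guard Abort threshold: integration stops with an error naming the
#'   time if any component is non-finite or exceeds this value (nM).
#' @return A `grn_trajectory` data frame (`time_min`, `day`, state columns).
#' @examples
#' # scalar test problem y' = -y(t - 1): y(t) = 1 - t on [0, 1]
#' tr <- integrate_dde(function(t, y, ylag) -ylag, 1, delta = 1,
#'                     horizon = 1, step = 0.1)
#' tr[[3]][nrow(tr)]   # 0 up to rounding
#' @export
integrate_dde <- function(rhs, y0, delta, horizon, step, var_names = NULL,
                          model = "dde", guard = 1e9) {
  if (delta < 0 || horizon <= 0 || step <= 0) {
    stop("delta must be >= 0 and horizon, step > 0")
  }
  if (delta > 0 && step > delta + 1e-12) {
    stop("step must not exceed the delay (method of steps)")
  }
  y0 <- as.numeric(y0)
  m <- length(y0)
  nstep <- ceiling(horizon / step - 1e-9)
  times <- c(seq_len(nstep) - 1, horizon / step) * step
  times[nstep + 1] <- horizon
  Y <- matrix(NA_real_, nstep + 1, m)
  Y[1, ] <- y0

  # Lag lookup. Stage lag times always satisfy tl <= t_k (step <= delta), so
  # they index the uniform part of the grid; the enclosing interval is found
  # arithmetically.
  k <- 1L
  lag_state <- function(tl) {
    if (delta == 0) return(NULL)
    if (tl <= 0) return(y0)
    j <- min(floor(tl / step + 1e-9) + 1, k)
    if (j >= k) return(Y[k, ])
    w <- (tl - times[j]) / (times[j + 1] - times[j])
    (1 - w) * Y[j, ] + w * Y[j + 1, ]
  }
  frhs <- if (delta == 0) {
    function(t, y) rhs(t, y, y)
  } else {
    function(t, y) rhs(t, y, lag_state(t - delta))
  }

  for (k_i in seq_len(nstep)) {
    k <- k_i
    t0 <- times[k]
    h <- times[k + 1] - t0
    y <- Y[k, ]
    k1 <- frhs(t0, y)
    k2 <- frhs(t0 + h / 2, y + h / 2 * k1)
    k3 <- frhs(t0 + h / 2, y + h / 2 * k2)
    k4 <- frhs(t0 + h, y + h * k3)
    ynew <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(ynew)) || any(abs(ynew) > guard)) {
      stop(sprintf("integration diverged at t = %.6g min", times[k + 1]))
    }
    Y[k + 1, ] <- ynew
  }
  if (!is.null(var_names)) colnames(Y) <- var_names else
    colnames(Y) <- paste0("y", seq_len(m))
  .make_trajectory(times, Y, model, step, delta)
}

# Model-level simulation wrappers ---------------------------------------------

#' Post-germination initial state
#'
#' The experimentally derived initial concentrations used for all full-model
#' simulations: AP1 0.00056, LFY 0.68, SOC1 33.3, FD 0.431, AGL24 27.69,
#' FT 0.00056 nM.
#'
#' @return Named numeric length-6 vector in model order.
#' @export
germination_state <- function() {
  c(AP1 = 0.00056, LFY = 0.68, SOC1 = 33.3, FD = 0.431, AGL24 = 27.69,
    FT = 0.00056)
}

#' Simulate the full six-gene delay model
#'
#' @param p A `grn_parameters` object.
#' @param inputs A `grn_inputs` object.
#' @param init Initial state (length 6); defaults to [germination_state()].
#' @param horizon_days Simulation horizon (days).
#' @param step_min Integration step (min).
#' @param delta_min Delay (min); defaults to the parameter set's delay.
#' @return A `grn_trajectory`.
#' @export
simulate_full <- function(p, inputs, init = germination_state(),
                          horizon_days = 100, step_min = 1,
                          delta_min = p$delta_min) {
  stopifnot(length(init) == 6)
  rhs <- .full_rhs_fast(p, inputs)
  integrate_dde(rhs, init, delta = delta_min, horizon = horizon_days * 1440,
                step = step_min, var_names = .state_names6, model = "full")
}

# Validation-free right-hand side used inside the integrator loop: constants
# are hoisted out of the closure and, for constant inputs, the SVP/FLC
# repression factors are precomputed. Agrees with full_rhs exactly.
.full_rhs_fast <- function(p, inputs) {
  b <- p$beta; K <- p$K; d <- p$d; n <- p$n
  Kn1 <- K[1]^n
  const_inputs <- inputs$mode == "constant"
  if (const_inputs) {
    lv <- inputs$levels
    kp34 <- (K[11] / (lv[["x7"]] + K[11])) * (K[12] / (lv[["x8"]] + K[12]))
    prod6 <- b[12] * (K[15] / (lv[["x9"]] + K[15])) * (K[16] / (lv[["x10"]] + K[16]))
  }
  function(t, y, ylag) {
    if (!const_inputs) {
      iv <- eval_inputs(inputs, t)
      kp34 <- (K[11] / (iv[["x7"]] + K[11])) * (K[12] / (iv[["x8"]] + K[12]))
      prod6 <- b[12] * (K[15] / (iv[["x9"]] + K[15])) * (K[16] / (iv[["x10"]] + K[16]))
    }
    x6d <- ylag[6]
    y2n <- y[2]^n
    c(b[1] * y2n / (y2n + Kn1) + b[2] * y[4] / (y[4] + K[2]) +
        b[3] * x6d / (x6d + K[3]) - d[1] * y[1],
      b[4] * y[1] / (y[1] + K[4]) + b[5] * y[3] / (y[3] + K[5]) +
        b[6] * y[5] / (y[5] + K[6]) - d[2] * y[2],
      (b[7] * y[3] / (y[3] + K[7]) + b[8] * y[5] / (y[5] + K[8]) +
         b[9] * (y[4] / (y[4] + K[9])) * (x6d / (x6d + K[10]))) * kp34 -
        d[3] * y[3],
      b[10] * y[2] / (y[2] + K[13]) - d[4] * y[4],
      b[11] * y[3] / (y[3] + K[14]) - d[5] * y[5],
      prod6 - d[6] * y[6])
  }
}

#' Simulate the reduced three-gene model
#'
#' Integrates the AP1/LFY/SOC1 system with `deSolve::ode` (lsoda) on a
#' regular output grid.
#'
#' @param p A `grn_parameters` object.
#' @param inputs Constant-mode `grn_inputs` (used to derive the reduced
#'   constants), or a precomputed `grn_derived` object.
#' @param init Initial state (length 3, `AP1, LFY, SOC1`).
#' @param horizon_days Simulation horizon (days).
#' @param step_min Output grid spacing (min).
#' @return A `grn_trajectory`.
#' @export
simulate_reduced <- function(p, inputs, init, horizon_days = 100,
                             step_min = 1) {
  stopifnot(length(init) == 3)
  dc <- if (inherits(inputs, "grn_derived")) inputs else derive_constants(p, inputs)
  times <- seq(0, horizon_days * 1440, by = step_min)
  out <- deSolve::ode(y = as.numeric(init), times = times,
                      func = function(t, y, parms) list(reduced_rhs(t, pmax(y, 0), dc, p)),
                      parms = NULL, method = "lsoda", hmax = 1440)
  states <- out[, -1, drop = FALSE]
  colnames(states) <- .state_names3
  .make_trajectory(out[, 1], states, "reduced", step_min, 0)
}

#' Simulate the two-gene AP1/LFY motif
#'
#' @param mp A `grn_motif` object.
#' @param init Initial state (length 2, `AP1, LFY`), nM.
#' @param horizon_days Simulation horizon (days).
#' @param step_min Output grid spacing (min).
#' @return A `grn_trajectory`.
#' @export
simulate_motif <- function(mp, init, horizon_days = 100, step_min = 1) {
  stopifnot(length(init) == 2)
  times <- seq(0, horizon_days * 1440, by = step_min)
  out <- deSolve::ode(y = as.numeric(init), times = times,
                      func = function(t, y, parms) list(motif_rhs(t, pmax(y, 0), mp)),
                      parms = NULL, method = "lsoda", hmax = 1440)
  states <- out[, -1, drop = FALSE]
  colnames(states) <- c("AP1", "LFY")
  .make_trajectory(out[, 1], states, "motif", step_min, 0)
}
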