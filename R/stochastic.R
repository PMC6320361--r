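# Euler-Maruyama simulation of the stochastic AP1/LFY motif with additive
# or multiplicative white noise, ensemble switching statistics, and the
# stochastic-Lyapunov mean-square stability checker.
#
# Reproducibility: increments are drawn in fixed chunks of .sde_chunk steps
# from a (path, chunk) counter scheme seeded off the master seed, so path j
# receives the same noise regardless of ensemble size or chunk traversal.

.sde_chunk <- 4096L

.sde_seed <- function(master, path, chunk) {
  as.integer((as.numeric(master) + 100003 * path + 257 * chunk) %% 2147483647)
}

# increments for one path and one chunk: matrix m x 2 of N(0, dt) draws
.sde_increments <- function(master, path, chunk, m, dt) {
  seed <- .sde_seed(master, path, chunk)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(stats::rnorm(2 * m, sd = sqrt(dt)), m, 2)
}

#' Stochastic simulation configuration
#'
#' @param noise `"additive"` (constant diffusion `sigma_i dW_i`, units
#'   nM/sqrt(min)) or `"multiplicative"` (diffusion proportional to the
#'   distance from a reference state, `sigma_i (x_i - xref_i) dW_i`, units
#'   1/sqrt(min)).
#' @param sigma1,sigma2 Non-negative noise amplitudes for AP1 and LFY.
#' @param reference Length-2 reference state for multiplicative noise
#'   (defaults to the origin).
#' @param dt_min Euler-Maruyama step (min).
#' @param horizon_days Simulation horizon (days).
#' @param n_paths Ensemble size.
#' @param seed Master seed (integer).
#' @return Object of class `sde_config`.
#' @export
sde_config <- function(noise = c("additive", "multiplicative"),
                       sigma1 = 0.05, sigma2 = 0.05, reference = c(0, 0),
                       dt_min = 0.5, horizon_days = 50, n_paths = 100,
                       seed = 1) {
  noise <- match.arg(noise)
  if (sigma1 < 0 || sigma2 < 0) stop("noise amplitudes must be non-negative")
  if (dt_min <= 0 || horizon_days <= 0) stop("step and horizon must be positive")
  if (n_paths < 1) stop("ensemble size must be at least 1")
  structure(list(noise = noise, sigma = c(sigma1, sigma2),
                 reference = as.numeric(reference), dt_min = dt_min,
                 horizon_days = horizon_days, n_paths = as.integer(n_paths),
                 seed = as.integer(seed)),
            class = "sde_config")
}

# core stepping routine, vectorised across paths.
# Returns list(x1, x2 = final states, clamped = clamp counter,
#              snapshots = list(times_min, x1 matrix, x2 matrix))
.em_run <- function(config, initial, mp, paths, record_every = NULL) {
  dt <- config$dt_min
  nstep <- ceiling(config$horizon_days * 1440 / dt)
  npath <- length(paths)
  s1 <- config$sigma[1]; s2 <- config$sigma[2]
  mult <- config$noise == "multiplicative"
  r1 <- config$reference[1]; r2 <- config$reference[2]
  x1 <- rep(initial[1], npath); x2 <- rep(initial[2], npath)
  clamped <- 0L
  b1F2 <- mp$beta1 * mp$F2; b4F1 <- mp$beta4 * mp$F1
  K1n <- mp$K1^mp$n; n <- mp$n
  rec <- !is.null(record_every)
  if (rec) {
    rec_idx <- seq(0, nstep, by = record_every)
    R1 <- matrix(NA_real_, length(rec_idx), npath)
    R2 <- matrix(NA_real_, length(rec_idx), npath)
    R1[1, ] <- x1; R2[1, ] <- x2
    ri <- 2L
  }
  step <- 0L
  chunk <- 0L
  while (step < nstep) {
    m <- min(.sde_chunk, nstep - step)
    dW <- lapply(seq_len(npath), function(j)
      .sde_increments(config$seed, paths[j], chunk, m, dt))
    dW1 <- vapply(dW, function(w) w[, 1], numeric(m))
    dW2 <- vapply(dW, function(w) w[, 2], numeric(m))
    if (m == 1) { dW1 <- matrix(dW1, 1); dW2 <- matrix(dW2, 1) }
    for (i in seq_len(m)) {
      xn2 <- x2^n
      drift1 <- b1F2 * xn2 / (xn2 + K1n) - mp$d1 * x1
      drift2 <- b4F1 * x1 / (x1 + mp$K4) - mp$d2 * x2
      g1 <- if (mult) s1 * (x1 - r1) else s1
      g2 <- if (mult) s2 * (x2 - r2) else s2
      x1 <- x1 + drift1 * dt + g1 * dW1[i, ]
      x2 <- x2 + drift2 * dt + g2 * dW2[i, ]
      neg <- x1 < 0
      if (any(neg)) { clamped <- clamped + sum(neg); x1[neg] <- 0 }
      neg <- x2 < 0
      if (any(neg)) { clamped <- clamped + sum(neg); x2[neg] <- 0 }
      if (any(!is.finite(x1)) || any(!is.finite(x2))) {
        stop(sprintf("SDE state non-finite at step %d", step + i))
      }
      step_i <- step + i
      if (rec && ri <= length(rec_idx) && step_i == rec_idx[ri]) {
        R1[ri, ] <- x1; R2[ri, ] <- x2; ri <- ri + 1L
      }
    }
    step <- step + m
    chunk <- chunk + 1L
  }
  out <- list(x1 = x1, x2 = x2, clamped = clamped)
  if (rec) {
    out$snapshots <- list(times_min = rec_idx * dt, x1 = R1, x2 = R2)
  }
  out
}

#' Euler-Maruyama sample path of the stochastic motif
#'
#' One realisation of the stochastic AP1/LFY motif
#' `dx = f(x) dt + g(x) dW` with independent Wiener increments
#' `dW_i ~ N(0, dt)`. With zero noise the recursion is exactly the
#' deterministic explicit-Euler scheme. States are clamped at zero after
#' each step (additive noise can drive concentrations negative, where the
#' Hill kinetics are meaningless); the number of clamped components is
#' recorded on the trajectory.
#'
#' @param config An `sde_config` (with `n_paths = 1`; only the first path
#'   stream is used).
#' @param initial Length-2 initial state (`AP1, LFY`), nM.
#' @param mp A `grn_motif` object.
#' @param record_every Record the state every this many steps (default 1).
#' @return A `grn_trajectory` with attributes `clamped` (count) and
#'   `seed`.
#' @export
euler_maruyama <- function(config, initial, mp, record_every = 1L) {
  stopifnot(inherits(config, "sde_config"), length(initial) == 2)
  run <- .em_run(config, initial, mp, paths = 1L, record_every = record_every)
  sn <- run$snapshots
  tr <- .make_trajectory(sn$times_min,
                         cbind(AP1 = sn$x1[, 1], LFY = sn$x2[, 1]),
                         model = paste0("motif_sde_", config$noise),
                         step = config$dt_min, delta_min = 0)
  attr(tr, "clamped") <- run$clamped
  attr(tr, "seed") <- config$seed
  tr
}

#' Stochastic ensemble of the motif with switching statistics
#'
#' Runs `n_paths` Euler-Maruyama realisations from a common initial state,
#' classifies each endpoint (`"flowering"` if AP1 ends above half the
#' non-trivial stable level, `"trivial"` if below twice the saddle level,
#' `"unresolved"` otherwise), and records periodic state snapshots from
#' which temporal histograms can be built.
#'
#' @param config An `sde_config`.
#' @param initial Length-2 initial state (`AP1, LFY`), nM.
#' @param mp A `grn_motif` object (must admit the bistable configuration
#'   for the labels to be meaningful).
#' @param snapshot_every Record ensemble snapshots every this many steps.
#' @return Object of class `grn_ensemble`: `endpoints` (n x 2 matrix),
#'   `labels`, `switching_fraction` (share of flowering paths), `clamped`
#'   count, and `snapshots` (times + state matrices).
#' @export
run_ensemble <- function(config, initial, mp, snapshot_every = 200L) {
  stopifnot(inherits(config, "sde_config"))
  eq <- .motif_equilibria(mp)
  run <- .em_run(config, initial, mp, paths = seq_len(config$n_paths),
                 record_every = snapshot_every)
  endpoints <- cbind(AP1 = run$x1, LFY = run$x2)
  if ("flowering" %in% names(eq$states)) {
    hi <- 0.5 * eq$states$flowering[["AP1"]]
    lo <- 2 * eq$states$saddle[["AP1"]]
    labels <- ifelse(endpoints[, 1] >= hi, "flowering",
                     ifelse(endpoints[, 1] <= lo, "trivial", "unresolved"))
  } else {
    labels <- rep("trivial", nrow(endpoints))
  }
  structure(list(endpoints = endpoints, labels = labels,
                 switching_fraction = mean(labels == "flowering"),
                 clamped = run$clamped,
                 snapshots = run$snapshots,
                 config = config),
            class = "grn_ensemble")
}

#' @export
print.grn_ensemble <- function(x, ...) {
  cat(sprintf("Stochastic motif ensemble: %d paths, %s noise, sigma = (%g, %g)\n",
              x$config$n_paths, x$config$noise, x$config$sigma[1], x$config$sigma[2]))
  print(table(x$labels))
  cat(sprintf("  switching fraction %.3f, %d clamp events\n",
              x$switching_fraction, x$clamped))
  invisible(x)
}

#' Temporal histogram of an ensemble
#'
#' Bins the recorded ensemble snapshots in time and concentration, giving
#' the time-resolved distribution of one variable across paths (long
#' format, ready for CSV export or plotting).
#'
#' @param ens A `grn_ensemble`.
#' @param variable `"AP1"` or `"LFY"`.
#' @param value_breaks Concentration bin edges (nM); defaults to 30 bins
#'   spanning the observed range.
#' @return Data frame `time_min`, `bin_lower`, `bin_upper`, `count`.
#' @export
temporal_histogram <- function(ens, variable = c("AP1", "LFY"),
                               value_breaks = NULL) {
  variable <- match.arg(variable)
  M <- if (variable == "AP1") ens$snapshots$x1 else ens$snapshots$x2
  if (is.null(value_breaks)) {
    value_breaks <- seq(min(M), max(M) * (1 + 1e-9), length.out = 31)
  }
  times <- ens$snapshots$times_min
  out <- do.call(rbind, lapply(seq_along(times), function(i) {
    cnt <- tabulate(findInterval(M[i, ], value_breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE),
                    nbins = length(value_breaks) - 1)
    data.frame(time_min = times[i],
               bin_lower = value_breaks[-length(value_breaks)],
               bin_upper = value_breaks[-1],
               count = cnt)
  }))
  rownames(out) <- NULL
  out
}

#' Ensemble second moments about a point
#'
#' Mean squared displacement of each component about a reference point at
#' every snapshot time; used to corroborate the mean-square stability
#' conditions empirically.
#'
#' @param ens A `grn_ensemble`.
#' @param about Length-2 reference point (default the origin).
#' @return Data frame `time_min`, `m2_AP1`, `m2_LFY`.
#' @export
ensemble_second_moment <- function(ens, about = c(0, 0)) {
  sn <- ens$snapshots
  data.frame(time_min = sn$times_min,
             m2_AP1 = rowMeans((sn$x1 - about[1])^2),
             m2_LFY = rowMeans((sn$x2 - about[2])^2))
}

#' Mean-square stability check for the multiplicative-noise motif
#'
#' The origin of the multiplicative-noise motif is locally asymptotically
#' stable in probability when `sigma_i < sqrt(2 d_i)` for both components.
#' The certificate is the quadratic Lyapunov function
#' `V = (theta*x1^2 + x2^2)/2`, which works for any
#' `theta > (beta4*F1/K4)^2 / ((2d1 - sigma1^2)(2d2 - sigma2^2))`, the
#' cross term being absorbed by Young's inequality with any `epsilon` in
#' the admissible window.
#'
#' @param sigma1,sigma2 Noise amplitudes (1/sqrt(min)).
#' @param mp A `grn_motif` object.
#' @return Object of class `lyapunov_check`: the amplitudes, the bounds
#'   `sqrt(2 d_i)`, the condition truth value, the feasible `theta` lower
#'   bound, a chosen `theta`, and the corresponding `epsilon` window
#'   (`NULL` when the condition fails).
#' @export
ms_stability_check <- function(sigma1, sigma2, mp) {
  if (sigma1 < 0 || sigma2 < 0) stop("noise amplitudes must be non-negative")
  bounds <- c(sqrt(2 * mp$d1), sqrt(2 * mp$d2))
  ok <- sigma1 < bounds[1] && sigma2 < bounds[2]
  theta_lower <- NULL; eps_window <- NULL; theta <- NULL
  if (ok) {
    q <- mp$beta4 * mp$F1 / mp$K4
    theta_lower <- q^2 / ((2 * mp$d1 - sigma1^2) * (2 * mp$d2 - sigma2^2))
    theta <- 2 * theta_lower
    eps_window <- c(q / ((2 * mp$d2 - sigma2^2) * 1),
                    theta * (2 * mp$d1 - sigma1^2) / q)
    # epsilon window of the Young-inequality step, guaranteed non-empty
    # for theta strictly above the lower bound
  }
  structure(list(sigma = c(sigma1, sigma2), bounds = bounds,
                 stable = ok, theta_lower = theta_lower,
                 theta = theta, eps_window = eps_window),
            class = "lyapunov_check")
}

#' @export
print.lyapunov_check <- function(x, ...) {
  cat(sprintf("Mean-square stability: sigma = (%g, %g), bounds sqrt(2d) = (%.5g, %.5g)\n",
              x$sigma[1], x$sigma[2], x$bounds[1], x$bounds[2]))
  if (x$stable) {
    cat(sprintf("  condition holds; any theta > %.6g certifies stability\n",
                x$theta_lower))
  } else {
    cat("  condition fails: no quadratic Lyapunov certificate of this form\n")
  }
  invisible(x)
}
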