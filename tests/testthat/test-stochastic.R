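test_that("zero noise reproduces the explicit Euler path exactly", {
  mp <- fix_motif()
  cfg <- sde_config("additive", 0, 0, dt_min = 0.5, horizon_days = 0.1,
                    seed = 4)
  tr <- euler_maruyama(cfg, c(0.3, 2), mp)
  x <- c(0.3, 2)
  for (i in seq_len(nrow(tr) - 1)) x <- x + motif_rhs(0, x, mp) * 0.5
  expect_equal(c(tr$AP1[nrow(tr)], tr$LFY[nrow(tr)]), x, tolerance = 1e-12)
  expect_identical(attr(tr, "clamped"), 0L)
})

test_that("paths are reproducible from the master seed", {
  mp <- fix_motif()
  cfg <- sde_config("additive", 0.05, 0.05, dt_min = 0.5, horizon_days = 0.05,
                    seed = 7)
  a <- euler_maruyama(cfg, c(0.2, 1.2), mp)
  b <- euler_maruyama(cfg, c(0.2, 1.2), mp)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # a single-path ensemble reuses the same stream as the lone path
  ens <- run_ensemble(sde_config("additive", 0.05, 0.05, dt_min = 0.5,
                                 horizon_days = 0.05, n_paths = 1, seed = 7),
                      c(0.2, 1.2), mp)
  expect_equal(unname(ens$endpoints[1, ]),
               c(a$AP1[nrow(a)], a$LFY[nrow(a)]))
})

test_that("multiplicative noise vanishes at the reference state", {
  mp <- fix_motif()
  cb <- motif_cubic(mp)
  ref <- c(map_equilibrium_relations(cb$positive_roots[2], mp)$AP1,
           cb$positive_roots[2])
  cfg <- sde_config("multiplicative", 0.1, 0.1, reference = ref,
                    dt_min = 0.5, horizon_days = 0.05, seed = 9)
  tr <- euler_maruyama(cfg, ref, mp)
  x <- ref
  for (i in seq_len(nrow(tr) - 1)) x <- x + motif_rhs(0, x, mp) * 0.5
  expect_equal(c(tr$AP1[nrow(tr)], tr$LFY[nrow(tr)]), x, tolerance = 1e-10)
})

test_that("clamping is inactive on paths that stay positive", {
  mp <- fix_motif()
  quiet <- euler_maruyama(sde_config("multiplicative", 0.05, 0.05,
                                     reference = c(0, 0), dt_min = 0.5,
                                     horizon_days = 0.2, seed = 3),
                          c(50, 100), mp)
  expect_identical(attr(quiet, "clamped"), 0L)
  noisy <- run_ensemble(sde_config("additive", 0.05, 0.05, dt_min = 0.5,
                                   horizon_days = 1, n_paths = 20, seed = 3),
                        c(0.01, 0.01), mp)
  expect_gt(noisy$clamped, 0)
})

test_that("sub-threshold starts cannot switch without noise", {
  mp <- fix_motif()
  ens <- run_ensemble(sde_config("additive", 0, 0, dt_min = 0.5,
                                 horizon_days = 10, n_paths = 5, seed = 1),
                      c(0.2, 1.2), mp)
  expect_equal(ens$switching_fraction, 0)
  expect_true(all(ens$labels == "trivial"))
})

test_that("switching grows with the noise amplitude", {
  mp <- fix_motif()
  frac <- vapply(c(0.005, 0.02, 0.05), function(s) {
    run_ensemble(sde_config("additive", s, s, dt_min = 0.5, horizon_days = 10,
                            n_paths = 100, seed = 42),
                 c(0.2, 1.2), mp)$switching_fraction
  }, 0)
  # monotone over the grid, allowing binomial fluctuation at 100 paths
  expect_true(all(diff(frac) > -0.1))
  expect_equal(frac[1], 0)
  expect_gt(frac[3], 0.3)
})

test_that("the ensemble mean approaches the deterministic path as noise shrinks", {
  mp <- fix_motif()
  det <- simulate_motif(mp, c(50, 100), horizon_days = 0.5, step_min = 10)
  det_end <- c(det$AP1[nrow(det)], det$LFY[nrow(det)])
  err <- vapply(c(0.05, 0.01), function(s) {
    ens <- run_ensemble(sde_config("additive", s, s, dt_min = 0.5,
                                   horizon_days = 0.5, n_paths = 200, seed = 3),
                        c(50, 100), mp, snapshot_every = 1440)
    sqrt(sum((colMeans(ens$endpoints) - det_end)^2))
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("temporal histograms partition the ensemble at every snapshot", {
  mp <- fix_motif()
  ens <- run_ensemble(sde_config("additive", 0.05, 0.05, dt_min = 0.5,
                                 horizon_days = 0.5, n_paths = 50, seed = 13),
                      c(0.2, 1.2), mp, snapshot_every = 360)
  h <- temporal_histogram(ens, "LFY")
  sums <- tapply(h$count, h$time_min, sum)
  expect_true(all(sums == 50))
  expect_true(all(table(ens$labels) >= 0))
  expect_length(ens$labels, 50)
})

test_that("the Lyapunov conditions evaluate the published bounds", {
  mp <- fix_motif()
  chk <- ms_stability_check(1.3, 0.18, mp)
  expect_equal(chk$bounds, c(1.31149, 0.18439), tolerance = 1e-4)
  expect_true(chk$stable)
  expect_gt(chk$theta_lower, 0)
  expect_lt(chk$eps_window[1], chk$eps_window[2])
  bad <- ms_stability_check(1.3, 0.2, mp)
  expect_false(bad$stable)
  expect_null(bad$theta_lower)
  # noise-free specialisation of the theta bound
  free <- ms_stability_check(0, 0, mp)
  expect_equal(free$theta_lower,
               (mp$beta4 * mp$F1 / mp$K4)^2 / (4 * mp$d1 * mp$d2))
})

test_that("second moments decay below the noise bounds and not above", {
  mp <- fix_motif()
  b <- sqrt(2 * c(mp$d1, mp$d2))
  run_m2 <- function(fac) {
    cfg <- sde_config("multiplicative", fac * b[1], fac * b[2],
                      reference = c(0, 0), dt_min = 0.25, horizon_days = 1 / 48,
                      n_paths = 500, seed = 17)
    ens <- run_ensemble(cfg, c(0.05, 0.05), mp, snapshot_every = 24)
    ensemble_second_moment(ens)
  }
  below <- run_m2(0.8)
  above <- run_m2(1.2)
  n <- nrow(below)
  # below both bounds: mean-square contraction in both components
  expect_lt(below$m2_AP1[n] / below$m2_AP1[1], 1e-3)
  expect_lt(below$m2_LFY[n] / below$m2_LFY[1], 1)
  # 20 % above the bounds, same Wiener increments: the LFY mean square is
  # amplified relative to the contracting run (paired comparison absorbs
  # the common path-to-path variability of the heavy-tailed estimator)
  expect_gt(above$m2_LFY[n] / below$m2_LFY[n], 1.1)
})
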