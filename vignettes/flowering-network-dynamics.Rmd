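---
title: "Dynamics of the Arabidopsis flowering network: models, analyses and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of the Arabidopsis flowering network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floradyn)
```

## The model

The floral transition of *Arabidopsis thaliana* is driven by a small gene
regulatory network: the meristem-identity genes AP1 and LFY activate each
other, SOC1 and AGL24 feed the LFY branch, FD and the leaf-borne signal FT
activate AP1 and SOC1, and the repressors SVP and FLC gate SOC1 and FT
transcription. `floradyn` implements this network at three levels of
resolution:

* the **full six-variable delay model** — protein concentrations
  `x1..x6` (AP1, LFY, SOC1, FD, AGL24, FT in nM) with Hill activation
  `x^n/(x^n + K^n)` and inhibition `K/(x + K)`; FT is produced in the leaf
  and acts on AP1 and SOC1 only after a transport delay (default half a
  day). The four SVP/FLC inputs are external signals, constant in all
  equilibrium work;
* the **reduced three-variable model** (AP1, LFY, SOC1), obtained by
  assuming FD, AGL24 and FT equilibrate instantaneously; their balances
  are substituted, producing the effective constants `V1..V8`, `S1..S12`,
  `u`, `U1`, `U2` available from `derive_constants()`;
* the **two-gene AP1/LFY motif**, the minimal bistable switch: mutual
  activation with external action factors `F1` (FT–FD on LFY) and `F2`
  (FT on AP1), inhibiting below 1 and activating above 1.

All rates are per minute and all concentrations nM. The delay is printed
in days and converted once at the interface (1 day = 1440 min); this
single-unit policy avoids the mixed-unit ambiguity that a day/minute
model invites.

### Parameters

The 34 kinetic constants (12 maximum transcription rates, 16 half-max
abundances, 6 degradation rates), the delay and the Hill cooperativity
`n = 3` ship as a JSON fixture and are returned by
`flowering_parameters()`. Estimation ranges (`parameter_ranges()`) are
attached for validation and for random draws: rates in [0.001, 200]
nM/min, abundances in [0.001, 2000] nM, degradation in [0.001, 1] /min,
delay in [0, 1] days.

The four constant input levels are **synthetic stand-ins**: the
experimental levels are not redistributable, and only the products
`k11(x7) k12(x8)` and `k15(x9) k16(x10)` enter the model. Both products
are recovered exactly by inverting the SOC1 and FT balances at the
published steady state, and each is split symmetrically between its two
inhibitors. Any other split of the products gives an identical model; the
packaged file is labelled `input_levels_synthetic.json` to make its
provenance explicit.

## Deterministic analyses

### Steady states

With constant inputs the FT level is explicit (`u`), FD and AGL24 are
explicit in LFY and SOC1, AP1 is explicit in LFY, and the LFY balance is
monotone and scalar for a given SOC1 level. The full equilibrium problem
therefore reduces to one scalar equation in SOC1, which
`solve_full_steady_state()` brackets on 2000 log-spaced points over
(1e-6, 1e6) nM and polishes to 1e-12. This replaces the degree-17
polynomial elimination that a symbolic treatment produces: the solution
set is the same, and every returned state is verified against the full
right-hand side (residual below 1e-8, scaled by max(state, 1) per
component). A boundary equilibrium at the origin is checked separately so
the pure-decay degenerate case is not missed by the positive log grid.

For the published constants the solver returns exactly one strictly
positive steady state, which the tests compare with the published table
to 0.05 %.

### Stability

The Jacobian of the full model is analytic, with the delayed FT channel
evaluated at its equilibrium value — the linearisation is then
delay-free, so local stability does not depend on the transport delay.
The FT row is autonomous and linear, so `lambda = -d6` always factors
out; `char_coefficients()` (Faddeev–LeVerrier) and `deflate_ft_factor()`
(synthetic division, remainder checked below 1e-9) produce the quintic
whose Routh–Hurwitz conditions decide stability. The letter-quantities of
a symbolic expansion are deliberately not reproduced: the numeric route is
cross-checked against an eigenvalue oracle, and the predicate–oracle
agreement is property-tested on 1000 random polynomials. Conditions
within 1e-9 (relative to the coefficient scale) of equality are reported
as `marginal` rather than forced to a verdict.

For the motif, stability of a positive equilibrium reduces to the closed
inequality `x2^(n-1) > n d1 d2 K1^n K4 / (b1 b4 F1 F2)`, with equality
exactly at the saddle-node; `motif_stability()` evaluates it directly and
the tests confirm the equality–discriminant equivalence numerically.

### Existence and bifurcation of the motif equilibria

For `n = 3` the positive motif equilibria are roots of a cubic with one
sign change structure that admits zero or two positive roots; the
dichotomy is decided by the discriminant `D3`. `find_critical_F()`
locates `D3 = 0` by bisection (bracket (1e-4, 10), absolute tolerance
1e-7 in F) for the three canonical scenarios: action on AP1 only
(`F1 = 1`), on LFY only (`F2 = 1`), and equal action (`F1 = F2`). The
discriminant is extremely steep in F (its value at an F rounded to five
decimals is already ~2 % of the `w4^2` scale), so the double-root
*multiplicity tag* — `|D3| < 1e-6 w4^2` — is only reached when F is
polished well beyond the reporting tolerance; the tests polish locally
before asserting the tag.

### Flowering threshold and flowering time

The saddle of the bistable motif is the flowering threshold: its stable
manifold separates initial conditions that decay to the trivial
(non-flowering) state from those that reach the high-AP1 flowering state.
Because the model never defines "flowering time" operationally, the
package adopts a declared convention: the first time AP1 reaches 50 % of
the non-trivial stable AP1 level. The threshold in initial LFY found on a
0.01 nM grid is insensitive to this convention (tests repeat the scan at
25 %, 50 % and 95 %), because crossing the saddle — not the subsequent
fast rise — is the rate-limiting event. The event itself is located by
the integrator (`deSolve::lsodar` with a root function), not by grid
inspection.

## Numerical integration

The full model is integrated by the **method of steps**: fixed-step
classical Runge–Kutta with the delayed FT value read from the stored
trajectory by linear interpolation. Because the step never exceeds the
delay, each lagged lookup falls in the already-computed past and each
segment is an ordinary RK4 step; with zero delay the scheme reduces
exactly to RK4 for the ODE. The default step is 1 min; RK4's linear
stability limit for the fastest mode (`d1 = 0.86`/min) is about 3.2 min,
so steps above ~3 min diverge — the divergence guard (abort when any
state is non-finite or above 1e9 nM, naming the time) turns this into a
clean error. Step-halving tests confirm at least fourth-order endpoint
convergence, and an adaptive DDE solver (`deSolve::dede`) serves as an
independent oracle. The history is constant and equal to the initial
state, as nothing else is specified for the pre-germination period.

The reduced model and the motif are non-delayed and smooth, so they are
integrated with `deSolve` (lsoda, internal step capped at one day — the
cap works around a dense-output failure when trajectories flatline at the
trivial state).

## Stochastic motifs

Two noise models extend the motif: **additive** noise
(`sigma_i dW_i`, in nM per sqrt-minute) perturbing each rate, and
**multiplicative** noise (`sigma_i (x_i - xref_i) dW_i`) proportional to
the distance from a reference state. `euler_maruyama()` implements the
standard Euler–Maruyama recursion; with zero noise it reproduces the
deterministic explicit-Euler path exactly, which the tests assert
bit-for-bit.

Numerical choices, stated once:

* **Clamping.** Additive noise can push concentrations negative, where
  Hill kinetics are meaningless; states are clamped at zero after each
  step and the clamp count is recorded. Paths that stay positive are
  unaffected (asserted in tests).
* **Step and horizon.** Default `dt = 0.5` min and 50-day horizon for
  ensembles. The switching decision for the 5 % additive noise level
  resolves within a few days (the LFY relaxation time is ~1 h and its
  stationary fluctuation, ~0.27 nM, dwarfs the 0.046 nM gap between the
  sub-threshold start and the saddle), so tests use 10-day horizons.
* **Reproducibility.** Increments are drawn in fixed 4096-step chunks
  from a (path, chunk) counter scheme seeded off the master seed, so
  path j's stream is independent of the ensemble size and identical
  across machines; a single-path run reproduces the first ensemble path.

`run_ensemble()` classifies endpoints by the AP1 level (above half the
flowering state: flowering; below twice the saddle level: trivial;
otherwise unresolved — the two attractors differ by three orders of
magnitude, so any intermediate cut gives the same labels) and reports the
switching fraction and periodic snapshots for temporal histograms. From
the sub-threshold start (0.2, 1.2) nM with 5 % additive noise, both
basins are populated — noise converts a deterministic non-flowering
initial condition into a finite flowering probability.

For multiplicative noise about the origin, the quadratic Lyapunov
function `V = (theta x1^2 + x2^2)/2` certifies local asymptotic
stability in probability whenever `sigma_i < sqrt(2 d_i)`;
`ms_stability_check()` evaluates the bounds, the admissible `theta`
(any value above `(b4 F1 / K4)^2 / ((2 d1 - sigma1^2)(2 d2 - sigma2^2))`)
and the Young-inequality window. The empirical corroboration in the
tests needs care: above the bound the *expected* square grows, but the
sample mean of a log-normal-like ensemble is heavy-tailed, so a naive
estimate at long horizons is dominated by rare paths. The tests therefore
use a short horizon (30 min), 500 paths, and a **paired comparison on
common Wiener increments**: the run at 120 % of the bounds must amplify
the LFY mean square relative to the contracting 80 % run (and the 80 %
run must contract in both components). The pairing absorbs the shared
path-to-path variability that would otherwise swamp the signal.

## Sensitivity analysis

`local_sensitivity()` computes normalised central-difference
sensitivities `S = (q/y) dy/dq` at 1 % relative perturbation for all 34
kinetic constants (the delay does not enter any steady state; `n` is
structural). Two output functionals are supported:

* the default **steady-state AP1 level**, and
* `ap1_transition_output()`, the **AP1 level at the nominal half-rise
  time** of the full-model trajectory.

The distinction matters scientifically. At equilibrium LFY (~452 nM) sits
far above `K1 = 9.82` nM, so the cooperative LFY→AP1 term is saturated
and the steady state is provably insensitive to `K1`
(`S ≈ -3 (K1/LFY)^3 ≈ -3e-5`) and weakly sensitive to the other switch
constants. The constants that govern the *transition* — the
mutual-activation loop `b1, K1, b4, K4, b5, K5, d1` — only surface when
the output probes the rise itself; with the transition functional they
occupy the top ten ranks (of 34, the convention used throughout for "top
set"). Doubling the perturbation changes the leading sensitivities by
less than 10 %, and the top-five set is stable across 0.5–2 %
perturbations; rank order deep in the tail (|S| below 1e-4) is not
meaningful and is not asserted.

## Synthetic data

The generators stand in for the study's experimental inputs.
`generate_inputs()` draws the four input signals independently, either as
constants or as piecewise-linear time courses (uniform values at equally
spaced knots, linear in between, held at the boundary) — the same shape
as expression series interpolated from sampled data. Default value
ranges are [0, 2 × packaged level] per input. `draw_parameters()` draws
the kinetic constants **log-uniformly** within the estimation ranges —
the ranges span up to five decades, and uniform draws would concentrate
all mass in the top decade — with the delay uniform and `n` fixed at 3.
Across seeds the draws exercise both branches of the motif existence
dichotomy (zero and two positive equilibria), which the tests assert.

What the generators do *not* emulate: the actual SVP/FLC expression time
courses (only their piecewise-linear shape and non-negativity), any
correlation between parameters, or measurement noise. Tests passing on
generated data therefore demonstrate correctness of the machinery under
the model's own assumptions, not agreement with new experimental data.

## Problem sizes used by the test-suite and acceptance runs

Deterministic: full-model runs use a 2-min step over at most 100 days;
the scalar steady-state reduction uses the 2000-point log grid (200 when
a hint restricts the bracket, as in the sensitivity scan). Stochastic:
ensembles of 100 paths over 10 days (switching), 200 paths over half a
day (weak-convergence), and 500 paths over 30 min (mean-square pairing),
all at `dt = 0.25–0.5` min. These sizes were chosen as the smallest at
which the respective statistics are stable under seed changes.

## Known limitations

* The delay enters only through the trajectory, not the stability
  analysis; delay-dependent (quasi-polynomial) spectra are out of scope,
  consistent with the delay-free linearisation being exact here.
* No bifurcation analysis is attempted for the full six-variable system;
  the saddle-node machinery is specific to the motif cubic (`n = 3`).
  For general `n` only the zero-or-two positive-root statement holds.
* The stochastic layer covers the motif only; chemical-Langevin-type
  noise for the full model is not implemented.
* Parameter estimation from expression data is out of scope; the
  constants are taken as printed, and the synthetic input levels
  reproduce the published equilibrium by construction, not from data.
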