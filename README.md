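# floradyn

Deterministic and stochastic dynamics of the *Arabidopsis thaliana*
flowering gene regulatory network.

## The problem

The switch from vegetative growth to flowering in *Arabidopsis* is
controlled by a small network of meristem-identity genes — AP1, LFY, SOC1,
FD, AGL24 and FT — under repression by SVP and FLC. A published dynamic
model describes the six internal protein concentrations `x1..x6` (nM) with
delay differential equations built from Hill kinetics,

```
dx1/dt = b1 g1^n(x2) + b2 g2(x4) + b3 g3(x6(t - D)) - d1 x1
dx2/dt = b4 g4(x1) + b5 g5(x3) + b6 g6(x5)          - d2 x2
dx3/dt = [b7 g7(x3) + b8 g8(x5) + b9 g9(x4) g10(x6(t - D))] k11(x7) k12(x8) - d3 x3
dx4/dt = b10 g13(x2) - d4 x4
dx5/dt = b11 g14(x3) - d5 x5
dx6/dt = b12 k15(x9) k16(x10) - d6 x6
```

with activation `g_j^n(x) = x^n / (x^n + K_j^n)`, inhibition
`k_j(x) = K_j / (x + K_j)`, a transport delay `D` for FT moving from leaf
to meristem, and four external inputs (SVP/FLC in meristem and leaves).
This package implements that model and the analyses around it for anyone
studying bistable genetic switches and floral transition timing:

- steady states of the full system (scalar reduction + bracketing) and
  their Routh–Hurwitz / eigenvalue stability;
- the reduced three-gene (AP1/LFY/SOC1) model obtained by equilibrating
  FD, AGL24 and FT;
- the two-gene AP1/LFY motif with external action factors `F1`, `F2`,
  whose positive equilibria solve the cubic
  `(w1 + w2 F2) x^3 - w3 F1 F2 x^2 + w4 = 0`
  (`w1 = d1 d2 K4`, `w2 = d2 b1`, `w3 = b1 b4`, `w4 = d1 d2 K1^3 K4`);
  its saddle-node bifurcation is located from the discriminant
  `D3 = w4 (4 (w3 F1 F2)^3 - 27 (w1 + w2 F2)^2 w4)`;
- flowering thresholds and flowering times in the bistable motif;
- Euler–Maruyama simulation of the motif with additive or multiplicative
  white noise, ensemble switching statistics, and the stochastic-Lyapunov
  mean-square stability condition `sigma_i < sqrt(2 d_i)`;
- local parameter sensitivity ranking and synthetic input/parameter
  generators.

All published kinetic constants ship as a machine-readable fixture. The
four external input levels are not redistributable; the packaged levels
(`inst/extdata/input_levels_synthetic.json`) are synthetic stand-ins
calibrated so the model reproduces the published steady state exactly.

## Worked example

```r
library(floradyn)

p   <- flowering_parameters()      # published kinetic constants
inp <- default_input_levels()      # calibrated constant inputs

# unique positive steady state of the full model, and its stability
ss <- solve_full_steady_state(p, inp)[[1]]
ss
#> Steady state (nM): AP1=121.567, LFY=452.395, SOC1=827.835, FD=1113.88,
#>   AGL24=86881.3, FT=2.037
#>   residual 0, strictly positive
stability_report(ss, p, inp)
#> Stability report (full model steady state)
#>   quintic coefficients: 0.97641 0.102583 0.00213829 1.20037e-05 9.96692e-09
#>   Routh-Hurwitz verdict: stable  | eigenvalue oracle: stable
#>   max Re(lambda): -0.000999988 per min

# saddle-node of the AP1/LFY motif under equal FT / FT-FD action
find_critical_F("subsystem3", p)
#> Saddle-node of the AP1/LFY motif (subsystem3): F = 0.211559
#>   double LFY root 12.0929 nM, bisection tol 1e-07

# bistable motif at the best-match action factors
mp <- motif_params(p, F1 = 1.3445, F2 = 1.0476)
motif_cubic(mp)
#> Motif steady-state cubic at F1 = 1.3445, F2 = 1.0476
#>   discriminant 5.66662e+14 -> 2 positive root(s)
#>   positive LFY roots: 1.2463, 452.389

# smallest initial LFY (at AP1 = 0.24 nM) that still flowers
flowering_threshold(mp)$threshold
#> [1] 1.25
```

The steady state is the flowering attractor: AP1 at 121.6 nM marks the
committed floral meristem, and the negative leading eigenvalue confirms it
is reached asymptotically. The motif's two positive LFY equilibria (1.25
and 452 nM) are the flowering threshold (a saddle) and the flowering state;
initial LFY below 1.25 nM decays to the non-flowering trivial state.

A command-line front end with the same operations is installed at
`inst/cli/floradyn.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "floradyn.R", package = "floradyn"))')" \
    steady-state --out report.json
```

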