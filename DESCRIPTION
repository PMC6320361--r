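Package: floradyn
Title: Deterministic and Stochastic Dynamics of the Arabidopsis Flowering
    Gene Regulatory Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the six-gene delay-differential model of
    floral transition in Arabidopsis thaliana and its reduced three-gene and
    two-gene (LFY/AP1) motifs. Provides Hill-kinetics primitives and a
    parameter registry, a method-of-steps integrator for the delayed system,
    steady-state solvers, Routh-Hurwitz and eigenvalue stability analysis,
    saddle-node bifurcation detection via the cubic discriminant,
    flowering-threshold computation, Euler-Maruyama simulation of additive
    and multiplicative noise motifs with ensemble switching statistics, a
    stochastic Lyapunov mean-square-stability checker, local parameter
    sensitivity ranking, and synthetic input-signal and parameter generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
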