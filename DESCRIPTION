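Package: fickfem
Title: Finite Elements for Concentration-Dependent Fickian Drug Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models one-dimensional Fickian diffusion and cumulative drug
    release from thin composite films. Solves Fick's second law with a
    concentration-dependent diffusion coefficient D(phi) = D0*(1+delta*phi)^k
    using piecewise-linear finite elements in space, implicit Euler with
    lagged-coefficient (Picard) linearization in time, and a Thomas
    tridiagonal solver. Provides the closed-form Fourier series solution for
    constant diffusivity as benchmark and fitting model, a two-stage
    parameter-estimation pipeline (Nelder-Mead fit of D0 to the analytic
    release curve, then a grid search for the concentration-dependence
    parameter delta against the finite-element release profile), synthetic
    release-profile generation, convergence studies, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
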