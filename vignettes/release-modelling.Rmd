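---
title: "Modelling concentration-dependent Fickian release with fickfem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling concentration-dependent Fickian release with fickfem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fickfem)
```

## The physical model

A thin drug-loaded film of thickness $2L$ sits in a dissolution medium. The
film is thin enough that transport through its edges is negligible, so the
(normalized) drug concentration $\phi(x, t)$ obeys Fick's second law on the
cross-section $I = (-L, L)$:

$$\frac{\partial \phi}{\partial t}
  = \frac{\partial}{\partial x}\!\left(D(\phi)\,\frac{\partial \phi}{\partial x}\right),
  \qquad \phi(\pm L, t) = \phi_\infty(t), \qquad \phi(x, 0) = \phi_0 .$$

For highly polymerized carriers such as nanocellulose composites a constant
diffusion coefficient is unrealistic; `fickfem` uses the power-law form

$$D(\phi) = D_0\,(1 + \delta\,\phi)^k ,$$

with $D_0 > 0$ in $\mu\mathrm{m}^2/\mathrm{h}$, a dimensionless sensitivity
$\delta \ge -1$, and an integer exponent $k$ (1 or 2 in routine use). For
$\delta > -1$ the coefficient is bounded below by
$D_* = \min(D_0, D_0 (1+\delta)^k) > 0$ on the physical range
$\phi \in [0, 1]$ (`check_ellipticity()`), which guarantees that every linear
system solved below is symmetric positive definite. The degenerate edge
$\delta = -1$ is admitted with a warning because the calibration grid scans
it; there $D(1) = 0$ and failures surface as explicit errors, never as
silent `NaN`s.

The standard desorption configuration is $\phi_0 = 1$ (film uniformly
loaded) and $\phi_\infty = 0$ (perfect sink). The measured quantity is the
cumulative release fraction $M_t/M_\infty$; for constant $D$ it has the
classical Fourier form implemented by `analytic_release()`,

$$\frac{M_t}{M_\infty} = 1 - \frac{8}{\pi^2}\sum_{n=0}^{p}
  \frac{1}{(2n+1)^2}
  \exp\!\left(-\frac{D\,(2n+1)^2 \pi^2\,t}{4 L^2}\right),$$

which depends on $(t, D, L)$ only through $D t / L^2$. The truncation
default $p = 100$ leaves a remainder below $8/(\pi^2 \cdot 4 (p+1)) \approx
2\times 10^{-3}$ at $t = 0$ and far less for $t > 0$; the sum is
accumulated from the smallest terms upward and terms below $10^{-300}$ are
skipped, so large arguments underflow harmlessly. The truncation is fixed
rather than adaptive so that results are bit-reproducible across runs.

## Discretization

Space is discretized with piecewise-linear (P1) elements on a uniform mesh
of $M$ interior nodes ($h = 2L/(M+1)$, `build_mesh()`), time with implicit
Euler. Nonlinearity is handled by lagging the coefficient: the step from
$t_n$ advances by solving

$$(B + \Delta t_n \hat A(\phi_h^{n})) \, \alpha^{n+1} = b^n ,$$

where $B$ is the tridiagonal P1 mass matrix (diagonal $2h/3$, off-diagonal
$h/6$) and $\hat A(\phi_h^n)$ the stiffness matrix with $D$ frozen at the
previous state. Its entries are assembled from exact per-element integrals
of $D(\phi_h)$ (`element_diffusivity_integral()`): closed forms for
$k = 1, 2$, Gauss–Legendre with $\lceil (k+1)/2 \rceil$ points (still exact)
for larger $k$. We assemble from element integrals rather than transcribing
banded formulas because the element route is unambiguous and extends to any
$k$; the test suite reconciles it against the independently transcribed
$k = 1, 2$ band formulas and against blind adaptive quadrature. Each step is
one Thomas solve, $O(M)$ operations (`thomas_solve()`); a vanishing pivot is
reported as an error rather than repaired, since positive definiteness makes
it impossible for admissible inputs.

### Boundary treatment

Non-homogeneous surface concentrations enter through a lifting
$\lambda_h = \phi_\infty (e_0 + e_{M+1})$ carried by the two boundary
half-tent functions; the boundary nodes are always stored, so imposing
$\phi_\infty$ is an assignment into the nodal vector. The default
`mode = "consistent"` eliminates the Dirichlet rows of the full
$(M+2)$-node system exactly: the old boundary value enters the right-hand
side through the $h/6$ mass coupling and the new one through both the mass
coupling and the lagged stiffness coupling (an element integral, $-D/h$ in
the constant case). By construction this reduces exactly to the
homogeneous scheme when $\phi_\infty = 0$ and is stationary when
$\phi_\infty = \phi_0$. An alternative `mode = "lifted"` keeps the compact
lifted right-hand side $B\alpha^n - (B + \Delta t \hat A)\mu^{n+1}$ with
$\mu \in \mathbb{R}^M$ carrying $\phi_\infty$ in its first and last entries;
it coincides with the consistent mode whenever $\phi_\infty = 0$ (the only
regime used for calibration) and is retained for comparison studies with
non-zero or time-dependent surface data.

Time-dependent $\phi_\infty(t)$ — e.g. the empirical imperfect-sink rule
$\phi_\infty(t) = 1 - M_t/M_\infty$ built by `empirical_boundary()` — is
linearly interpolated to solver times and extrapolated as a constant beyond
its last sample, the simplest rule consistent with a pointwise definition.

### Initial state

The initial field is the $L^2$-projection of $\phi_0$ onto the mesh
(`l2_project_initial()`). The interior unknown of the lifted formulation is
$\phi - \lambda$, so the lifting's mass coupling is subtracted from the
projection right-hand side. Two consequences worth knowing:

* With boundary value $0$ (the desorption default) this is the plain
  zero-trace projection. For discontinuous data ($\phi_0 = 1$ against
  $\phi_\infty = 0$) that projection **overshoots**: nodal values reach
  $\approx 1.27$ near the surfaces, independent of $h$. This is the correct
  best-approximation of an incompatible initial/boundary pair, not a bug;
  all post-initial states stay within $[0, 1]$ to $10^{-8}$ under
  $\delta \ge 0$, and the film's total drug content decreases strictly
  monotonically.
* With boundary value equal to a constant $\phi_0$, the projected field is
  exactly the constant — a film in equilibrium stays put to machine
  precision.

### Picard depth

The scheme as used for calibration performs a single lagged solve per step
(`picard_iters = 1`): the linearization error is then $O(\Delta t)$, the
same order as the time discretization itself, so iterating buys accuracy
only in the constant multiplying $\Delta t$. `picard_iters > 1` re-assembles
from the newest iterate and stops when successive iterates agree to
$10^{-10}$ in the max norm; it is useful for stiff laws or large steps.

## Calibration pipeline

Calibration is deliberately staged, not joint:

1. **`fit_d0()`** minimizes
   $e_{\mathrm{ana}} = \sum_n (u_n - w_n(D_0))^2$, the misfit between the
   measured fractions $u_n$ and the constant-coefficient series at the
   measurement times, by Nelder–Mead on $\log_{10} D_0$ (positivity is
   structural; the objective is smooth and in practice unimodal). Starts at
   $D_0 \in \{1, 10, 100\}\,\mu\mathrm{m}^2/\mathrm{h}$ guard against the
   flat large-$D_0$ tail, with a relative objective tolerance of $10^{-10}$
   and the best converged start returned.
2. **`grid_search_delta()`** fixes $D_0$ and $k$, simulates the full
   nonlinear model for each candidate $\delta$ in a grid (default
   $\{-1, -0.3, -0.2, 0, 0.2, 0.3, 1\}$ on a mesh with $M = 31$), and picks
   the minimizer of $e_{\mathrm{num}} = \sum_n (u_n - v_n(\delta))^2$, where
   $v_n$ is the simulated release fraction
   $\int (\phi_h - \phi_0)\,dx \,/\, 2L(\phi_\infty - \phi_0)$ at the
   measurement times (`release_from_history()`, with the numerator
   integrated exactly by the trapezoidal rule, which is exact for P1
   fields). Ties are broken toward the smallest $|\delta|$, i.e. toward the
   simpler near-constant law. Values $\delta < -1$ are rejected as
   inadmissible rather than scored.

The solver grid for $e_{\mathrm{num}}$ is the measurement times refined so
that no step exceeds $1/200$ of the observation span — fine enough that the
time-discretization error is negligible against typical measurement scatter
while keeping a single grid evaluation at a few hundred Thomas solves.
Model comparisons are summarized by
`improvement_percent(e_ref, e_new)` $= 100\,(e_{\mathrm{ref}} -
e_{\mathrm{new}})/e_{\mathrm{new}}$, the relative excess error of the
reference over the competitor.

`reference_samples()` ships the published constants of the four
nanocellulose/nanoporous-silicon films (thicknesses $6.5$–$29.5\,\mu$m and
their fitted $D_0$ values); their measured release tables are not
redistributed with the package, so examples and tests use these constants
as generating parameters for synthetic stand-ins.

## What the synthetic generator does and does not emulate

`generate_profile()` mimics the structure of triplicate dissolution
experiments: a noiseless forward model (series or finite-element) sampled
at irregular times, plus independent additive Gaussian noise per replicate
on the fraction scale, optionally clipped to $[0, 1]$, averaged across
replicates, all reproducible from a seed. The default design takes 12
samples, geometrically front-loaded (`default_times(..., "early-dense")`,
ratio $0.7$) over a horizon with $D_0 T / L^2 \approx 3$, i.e. $\ge 99\%$
released — the informative region of the curve.

The generator does **not** emulate instrument calibration drift,
heteroscedastic or correlated errors, fractions exceeding 1 through assay
bias, wetting/swelling transients, or sampling-induced volume changes. A
passing recovery test therefore demonstrates that the pipeline inverts its
own forward model under idealized noise — a necessary check of the
numerics, not a validation against laboratory variability.

## Verification

Two independent routes guard the solver:

* **Matrix level.** Every assembled matrix is compared against blind
  adaptive quadrature of the basis-function integrals, and the $k = 1, 2$
  band formulas are reconciled with the element-integral assembly to
  $10^{-12}$ on random states. SPD factorizations are checked along whole
  trajectories.
* **Solution level.** For constant $D$ the finite-element release curve is
  compared with the Fourier series. Nested-refinement studies
  (`run_convergence_study()`, coarsest $M = 7$ with $\Delta t \propto h^2$
  for the spatial sweep, $M = 511$ for the temporal sweep, problem sizes
  chosen to finish in seconds) show the expected orders: $\approx 2$ in
  $h$, $\approx 1$ in $\Delta t$. At production resolution ($M = 255$,
  2000 uniform steps over one diffusion time) the release curve agrees
  with the series to a few $10^{-4}$ at the standard sampling design.

One startup effect deserves mention: with discontinuous initial/boundary
data the first few implicit-Euler steps carry an $O(\sqrt{D\,\Delta t})$
error in the release fraction (the discrete front is exponential where the
true one is Gaussian), so the discrepancy directly at $t_1$ is a few
$10^{-3}$ at the resolution above and decays like $n^{-1/2}$ over the next
steps. Reported release profiles live at measurement times — never at the
first internal solver steps — so this transient does not touch the
calibration pipeline; it is the reason comparisons are made at sampling
designs rather than at every internal time level.

## Limitations

* One-dimensional slab geometry; no edge leakage, no swelling or moving
  boundaries, and no temperature dependence of $D$.
* Power-law $D(\phi)$ only; exponential laws would need a new
  `element_diffusivity_integral()` (the quadrature fallback is written for
  polynomial integrands).
* Uniform meshes and first-order time stepping; the startup transient above
  is intrinsic to implicit Euler with incompatible data.
* Staged calibration: $\delta$ inherits whatever error the stage-one $D_0$
  carries; the two are not re-optimized jointly, by design, to match the
  two-stage experimental protocol the package reproduces.
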