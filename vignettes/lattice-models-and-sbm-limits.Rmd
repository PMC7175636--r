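---
title: "Critical lattice models, ancestral relations, and their super-Brownian limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical lattice models, ancestral relations, and their super-Brownian limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlattice)
```

## The models and their ancestral relations

All four models start from a single occupied site at the origin `o` of
`Z^d` and evolve a finite occupied set `T_t`. Steps are drawn from a
finite-range symmetric kernel `D` with sup-norm range `L` and isotropic
per-coordinate variance `sigma2_D` (the spread-out kernel
`uniform_box_kernel(d, L)` is the default family; any table passing
`validate_step_kernel()` is accepted).

* **Voter model** (continuous time): each voter at `y` imposes its opinion
  on site `x` at rate `D(x - y)`. Tracing an opinion backwards through the
  arrows of the graphical construction yields the *dual coalescing random
  walk* `W^{t,x}`, a rate-one `D`-walk; `x` is occupied at `t` exactly when
  its dual reaches the origin at time 0.
* **Contact process**: infected sites recover at rate 1 and emit infection
  arrows at rate `lambda * D(.)`; occupancy is equivalent to a
  recovery-free oriented arrow path from `(0, o)`.
* **Oriented percolation** (discrete time): bonds from `(n, x)` to
  `(n+1, x+e)` are independently occupied with probability `p * D(e)`.
* **Critical branching random walk**: each particle begets children by a
  finitely supported mean-one offspring law (variance `gamma`), displaced
  by independent kernel steps. It serves as the tractable surrogate for
  critical lattice trees, whose exact critical weighting is not computable.

Each model carries an ancestral relation `e_{s,t}(y, x)` — for the voter
model via the dual (`y = W^{t,x}_{(t-s)^+}`), for the contact process and
oriented percolation via oriented-path reachability, for branching random
walk via genealogical descent. The runtime-checkable axioms (reflexivity
exactly on occupied sites, occupied endpoints, root property, transitivity,
interpolation) are verified by `check_ar_axioms()` on realized samples.
Path regularity and measurability are properties of the probabilistic
construction, not of finite samples, so they are documented here and
excluded from the runtime report.

**Multi-occupancy.** For branching random walk the site projection of
descent is *not* transitive: two particles at one site can have different
ancestors, and realized counterexamples appear within a hundred
realizations. The ancestral system is therefore labelled by particle
(`brw_ancestral_system(real, labelled = TRUE)`, the default): a "site" is
`(position, particle index)` and the relation is a tree, so all axioms
hold. The site projection remains available (`labelled = FALSE`) and is
what the range and one-arm statistics use.

## Simulator design

The continuous-time simulators are exact event-driven constructions (no
time discretization), with per-event exponential clocks, implemented in
compiled code; all randomness flows through R's global generator, so
`set.seed()` (or the `seed` arguments) reproduces any run bit for bit.

**Lazy materialization.** Only Poisson arrows with an endpoint in the
currently occupied set are generated. For the voter model two thinned
streams are used — arrows *into* occupied targets (rate `|T|`) and
effective arrows *out of* occupied sources into unoccupied targets (the
both-endpoints-occupied duplicates of the second stream are discarded so
that every arrow is generated at its exact intensity). This is exact for
the set-valued trajectory, and sufficient for every dual walk anchored at
an occupied space-time point, because ancestral paths never leave the
occupied set: while the dual sits at a site, that site is occupied, and
every arrow into an occupied site is in the record. Dual walks anchored at
never-occupied sites are not supported by a simulated record (hand-built
fixture records, which are complete by construction, have no such
restriction). For the contact process, all arrows out of infected sources
are kept — arrows between two infected sites matter for ancestry even
though they do not change the infected set.

**Conventions.** Arrows at exactly the query time are included
(right-continuity); the dual holds its pre-jump site at the backward jump
time itself (left-continuity in backward time), with a `1e-9` tolerance so
that queries at exact event times are not thrown off by floating-point
round trips. Event-time ties have probability zero and are rejected by the
fixture constructor. Radii are Euclidean; the kernel range is a sup-norm
bound. The jump skeleton of a voter/contact ancestral system contains
*every* event time, not only the set-changing ones, because duals jump at
arrows between two occupied sites.

**Censoring.** Critical survival times have infinite mean, so every
simulator takes explicit caps (`sim_caps()`: `1e7` events, `1e6` sites by
default) and flags capped realizations as censored. Estimators resolve
censored replicates both ways and report a `[lower, upper]` bracket plus
the censoring fraction — silent truncation would bias exactly the
heavy-tailed quantities the limit theory is about.

## The super-Brownian side

The limit predictions are computed independently of the simulators:

* `canonical_survival()`, `yaglom_density()`, `v_lambda()` (in the
  overflow-safe `tanh` form), `laplace_integrated_mass()` and
  `small_mass_asymptotics()` are closed forms in the branching rate
  `gamma` and diffusion parameter `sigma0^2`.
* `solve_vd0(d)` integrates the radial blow-up problem
  `v'' + (d-1)/r v' = v^2`, `v(0) = a`, `v'(0) = 0` with an adaptive RK4
  whose step shrinks like the distance to blow-up, detects blow-up at
  `v = 1e8`, and recovers the remaining distance from the universal
  asymptotic `v ~ 6/(R-r)^2` (with the first curvature correction
  `6(d-1)/(5R) / (R-r)`). The scaling symmetry `v_d(0) = a R(a)^2`
  independent of `a` is both how the boundary value at 1 is normalized and
  a self-test; the error bound comes from Richardson step-halving. In one
  dimension the exact first integral `v'^2 = (2/3)(v^3 - a^3)` gives the
  independent quadrature oracle `vd0_quadrature_d1()`, which agrees with
  the solver to the requested tolerance.
* `escape_probability()` computes the walk's no-return probability for
  `d > 2` via `beta = 1/G`, `G` the Green-function integral
  `(2*pi)^{-d} \int (1 - D_hat(k))^{-1} dk`, with geometrically refined
  composite Gauss panels toward the integrable singularity at `k = 0`; a
  direct Monte-Carlo route with a local-CLT tail bound cross-checks it.
  For `d = 2` the value `2*pi*sigma2_D` is returned — the normalization
  the two-dimensional limit theory uses.
* `limit_constants()` assembles `(gamma, sigma0^2, s_D, v_d(0), beta_D)`
  per model. The constants `A`, `V`, `v` of the high-dimensional models
  are *inputs* with provenance flags: they are defined only as
  lace-expansion limits, so the package estimates `A` heuristically
  (`estimate_A()`, mean-mass plateau) or takes user values, and never
  pretends to compute them.
* `predicted_one_arm_constant()` and `predicted_spatial_moment()` dispatch
  the model-specific formulas and assert internally that they agree with
  the general form `sigma0^2 s_D v_d(0) / 2` under the model's mass
  normalization `m(t)` (`m_function()`).

## Finite-size behaviour the tests quantify

The limit theorems are asymptotic; at desk scale the tests measure and
report the distance still to go rather than hiding it:

* At `n = 100` the exact value of `n P(Z_n > 0)` for the critical binary
  law is 1.87916 (generating-function recursion; also recovered by the
  characteristic-function/FFT oracle in the tests): the Kolmogorov
  correction of order `log n / n` keeps it about 6% below the limit 2, and
  outside three Monte-Carlo standard errors at `5e5` replicates. The
  Yaglom rate estimator (inverse conditional mean) targets exactly the
  same number. The corresponding full-scale checks therefore fail their
  idealized bands by design honesty, with the recursion cross-check green.
* The voter one-arm product `r^2 eta_r` in `d = 3` reaches about
  0.63/0.73/0.85 of the predicted constant at `r = 10/15/20` and about
  0.9–1.05 by `r = 30–60`: the convergence trend is tested; equality at
  `r = 10` is not attainable.
* The modulus-of-continuity exceedance curve
  `P(Delta^{(n)}(rho) > C(rho^alpha + n^{-alpha}))` is bounded above by a
  multiple of `rho^beta + n^{-q}`, but nothing forces the empirical curve
  to *attain* the exponent: at `n` in `{64, 256}` it is dominated by the
  survival tail and nearly flat in `rho`, so the slope diagnostic reports
  a slope near zero. The exponent configuration used throughout is the
  most `rho`-sensitive admissible one: `alpha = 0.25`, `beta = 1`,
  `p = 16`, `kappa = 40` (the constraints are
  `(1-2 alpha)/(1+beta) >= 4/p` and `alpha < 1/2 - 2/kappa`), with
  threshold constant `C = 0.6`. `Delta^{(n)}(rho)` itself is estimated on
  the jump skeleton with documented anchor/breakpoint budgets (12 anchor
  times, 8 sites per time, 256 dual breakpoints) and is exact — verified
  against exhaustive enumeration — on instances small enough to exhaust.

## Choices where the design was open

* **Critical rates.** No closed form exists for `lambda_c` or `p_c`, and
  no numeric value is assumed. `estimate_lambda_c()` / `estimate_p_c()`
  return explicitly approximate bisection brackets driven by the decay of
  `t * theta(t)`; the reported bracket-end survival probabilities use a
  monotone thinning coupling (thin the higher-rate record's arrows by
  `lambda_1/lambda_2` and replay), so they are ordered pathwise. All
  contact-process and oriented-percolation experiments are parameterized
  by a user-supplied rate and documented as near-critical probes.
* **Interpolation tie-break.** The interpolation axiom guarantees an
  intermediate ancestor exists, not that it is unique; `interpolation_chain()`
  and `extract_ancestral_path()` take the lexicographically smallest
  candidate, making path extraction deterministic for every model (and
  exactly the unique dual path for the voter model).
* **Empty sets.** The capped Hausdorff-type metric uses the *sum* of the
  two directed deviations, capped at 1, with `d0(empty, K) = 1` for
  nonempty `K`; `d0(empty, empty) = 0` is forced by the metric axioms.
* **Oriented-percolation growth.** The identity "expected next-generation
  size equals `p |T_n|`" holds for occupied *bond* counts; the collapsed
  site process loses mass to coinciding targets, and the regression test
  is phrased accordingly.
* **First-integral residuals.** The solver's residual is checked through
  the exact `d = 1` first integral (machine-level) and through finite
  differences for `d > 1` (limited by the differentiation scheme, not the
  solver, hence a `1e-3` relative bound away from blow-up).

## Problem sizes

The test suite runs the full-scale study conditions where they are stated
(5e5 Galton–Watson replicates at generation 100, at least 1e4 Yaglom
survivors, 2e4 voter realizations to time 5, 3e4 one-arm replicates per
radius, 100 realizations per model for the axiom suites, 400 modulus
replicates per scale) and scaled-down versions elsewhere; each experiment
documents its replicate count and seed, and `scripts/acceptance.R`
re-derives the headline numbers from scratch from a single `--seed`.

## What these simulations do and do not show

The simulators *are* the models — there is no approximation in the
dynamics, only Monte-Carlo error, explicit censoring, and finite `n`, `t`,
`r`. What desk-scale agreement cannot establish is the asymptotic regime
itself: the high-dimensional theory (oriented percolation `d > 4`, lattice
trees `d > 8`) is out of numerical reach here, lattice trees are
represented by their branching-random-walk surrogate, and the
lace-expansion constants entering those predictions are user inputs, not
outputs. Within those limits, every closed-form prediction in the package
is exercised against an independent route (recursion, quadrature,
Fourier/Monte-Carlo pairs, duality identities) rather than against itself.
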