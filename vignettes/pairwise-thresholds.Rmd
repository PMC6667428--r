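---
title: "Pairwise SIR models on clustered regular networks: closures, fast variables and epidemic thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise SIR models on clustered regular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairwiseSIR)
```

## The model

`pairwiseSIR` implements pair-approximation (pairwise) models for SIR
epidemics on static regular networks of `N` nodes with common degree `n`,
per-link transmission rate `tau` (1/time), recovery rate `gamma` (1/time)
and global clustering coefficient `phi` (dimensionless, in [0, 1]). The
state variables are expected counts of singles `[S]`, `[I]` and of pairs
`[SI]`, `[SS]`, `[II]`, with pairs counted once in each direction; `[R]` and
the R-type pairs are implied by conservation. The unclosed equations are
exact for the underlying Markov chain; they involve the triples `[SSI]` and
`[ISI]`, which a *closure* expresses in terms of pairs and singles.

Three closures are provided (plus the classic unclustered one they all
reduce to at `phi = 0`):

* **Simple clustered closure.** The neighbour-state probability on the
  clustered fraction `phi` of triples is discounted by the pair correlation
  `C_AI = N[AI]/(n[A][I])`. It is the classic choice, but for `phi > 0` it
  fails the pair-level conservation `sum_A [ASI] = (n-1)[SI]`.
* **Improved closure** (full, over `{S, I, R}`): renormalises the clustered
  part so conservation holds exactly. It needs the R-type pairs, so it is
  provided for identity checking only and is not wired into an ODE system.
* **Compact improved closure**: the same renormalisation restricted to
  `{S, I}`, keeping the closed system five-dimensional. Conservation again
  holds exactly when the R-triple carries the unclustered part only (the
  clustered part excludes R by construction).

All counts are continuous expectations; no integrality is enforced
anywhere.

## Fast variables and the threshold

The ratios `alpha = [SI]/[I]` and `delta = [II]/[I]` relax much faster than
prevalence: starting from a small random seed they reach a
quasi-equilibrium `(alpha*, delta*)` while `[S]/N` is still essentially 1.
Since `d[I]/dt = gamma [I] (tau alpha / gamma - 1)`, the growth-rate
threshold is `R = tau alpha* / gamma`: the epidemic takes off iff `R > 1`.
The package implements, for both closures:

* the planar fast subsystem `rhs_fast()` and its invariant region
  `D = {0 <= alpha <= n, 0 <= delta <= n - alpha}`;
* null clines, the Bendixson (Dulac-rescaled) divergence, and the parameter
  bounds governing existence and global stability of the interior steady
  state (`stability_conditions()`): feasibility `phi < (n-2)/(n-1)`,
  Bendixson `phi < 2n/(3(n-1))` — the two bounds cross at `n = 6` — and the
  compact-improved repulsion condition `2 phi < (n-2)/(n-1)`;
* the quasi-equilibrium by two independent routes (`quasi_equilibrium()`):
  ODE relaxation from the fast-variable image of the standard initial
  conditions, and damped Newton iteration seeded by the asymptotic
  expansion;
* the steady-state cubic (`cubic_coefficients()`, `solve_steady_state()`):
  in `alpha` for the simple closure, in `delta` (mapped back to `alpha`)
  for the compact improved closure;
* first-order asymptotic expansions of the feasible root in powers of
  `phi` (`expansion()`), giving closed-form thresholds `threshold(...,
  "asymptotic")`.

```{r}
p <- model_params(N = 10000, n = 5, tau = 1, gamma = 1, phi = 0.5)
quasi_equilibrium(p, "simple")
solve_steady_state(cubic_coefficients(p, "simple"), p)
```

For comparison, the package also evaluates Keeling's quasi-equilibrium
correlation equation (`keeling_CSI_star()`; `n C*_SI` equals the cubic's
feasible root — the two formulations are the same equation under
`C_SI = alpha/n`), a next-generation-matrix `R0` built from the linearised
system with the fast variables at quasi-equilibrium (`ngm_R0()`), the
motif-closure formula `R0 = (n-1) tau / (tau + gamma + tau phi)`
(`li_R0()`), its percolation-theory twin (`miller_R0_regular()`, identical
to the motif formula's first-order expansion in `phi`), and a household
model with size-three cliques whose reproduction number `R*` decreases like
`phi^{-1/2}` (`household_R_star()`).

Two textbook-style formulas in the comparison suite required correction against independent numerics, and
the package follows the numerics: the first-order NGM coefficient `r1`
(its second bracket term is `xi alpha0 delta0 / n`, verified against the
exact `phi`-derivative of the eigenvalue), and the household `T2`
coefficient (which is `(1 + mu_T)/2 (1 - M(lambda_G))`; the `R*` value
itself is always computed from its defining product form, so only the
exposed decomposition is affected).

## Study conditions

The numerical experiments in the test-suite and in
`scripts/acceptance.R` use the reference conditions throughout:
`N = 10000`, `gamma = 1` (time in units of the infectious period),
`I0 = 1` seed placed uniformly at random — so all pair counts start at
their random-labelling values and all pair correlations start at 1 —
`t_max = 1000`, degrees `n` in 3..10, `tau` in 0.25..2 and clustering
`phi` in {0, 0.15, 0.3, 0.45, 0.6}. The deterministic pairwise model is
self-generating: no external data enter, and a run is reproducible
bit-for-bit. What these conditions do *not* probe is finite-size
stochasticity, degree heterogeneity, or how well any closure tracks a real
(simulated or observed) network epidemic; passing tests certify internal
consistency of the closed models and their analysis, not fidelity to
explicit network simulations, which are out of scope.

## Numerical choices

* **Integrator.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`. The
  fast-slow structure makes the closed system mildly stiff near `t = 0`;
  lsoda switches automatically. Tiny negative solver excursions (below
  `10 atol`) are clipped to zero before evaluating the right-hand side.
* **Degenerate divisions.** Closure terms are evaluated in factored form so
  that every `1/[I]` or `1/[I]^2` is multiplied by at least one power of
  `[SI]` or `[II]`; a term whose numerator is exactly zero is defined as
  zero. This matches the limits implicit in the closed equations and keeps
  the solver stable at extinction. The compact improved clustered terms are
  evaluated as `SS*SI*I/(SS*I + II*S)` and `SI*II*S/(SS*I + II*S)`, which
  are singularity-free on the relevant set.
* **Extinction and attack rate.** "Died out" means `[I] < 1e-6` (far below
  one individual). The final epidemic size is `(N - S(t_max))/N`, seeds
  included; the alternative `(S(0) - S(inf))/N` differs by `I0/N = 1e-4`,
  immaterial at the scales reported. Epidemic/no-epidemic classification
  for sweeps uses an attack-rate level of 0.01, well above `I0/N`.
* **Quasi-equilibrium convergence.** The relaxation route integrates in
  chunks of `10/min(gamma, tau)` until the residual satisfies
  `max|rhs| < 1e-10`, erroring (never silently accepting) beyond
  `t = 200/min(gamma, tau)`. The horizon is scaled by the slower of the
  two rates because near the feasibility boundary the subsystem's slowest
  eigenvalue is proportional to `tau`; with a `gamma`-only horizon,
  feasible small-`tau` corners of the study grid (e.g. `n = 3`,
  `tau = 0.25`, `phi = 0.45`) would need ~800 time units and fail
  spuriously. The Newton route declares convergence at residual `1e-13`
  and errors above `1e-10`. The two routes agree to well below `1e-6`
  across the study grid.
* **Root selection.** All cubic roots are computed with `polyroot`; a
  leading coefficient below `1e-12` relative magnitude (identically zero at
  `phi = 0` for the simple closure) downgrades the polynomial first. The
  feasible root is the one in `(0, n]`; if several qualify, the root
  closest to the first-order expansion — hence continuous with the
  `phi -> 0` limit `n - 2` — is chosen and a warning attached.
* **Null-cline poles.** Evaluation within `1e-9` of a singularity raises a
  domain error rather than returning a huge float; `phase_plane_report()`
  windows poles explicitly. At `phi = 0` the simple closure's
  `dalpha/dt = 0` cline degenerates to the vertical line `alpha = n - 2`
  and `nullclines()` refuses rather than divide by zero.
* **`C*_SI` root finding.** The correlation equation is solved on
  `(1e-9, 1 - 1e-9)` after clearing its denominator; the denominator's sign
  is monitored and a warning issued if it vanishes in-bracket (an edge
  regime that also gets a flag in `stability_conditions()`).
* **Region membership.** `D` is closed; `in_region_D()` uses non-strict
  inequalities with no tolerance. Invariance checks in the tests allow
  `1e-8` for solver round-off.

## Design choices that were genuinely open

* **Reconstructing the compact-improved closed system.** The closed
  five-dimensional system for the compact improved closure is obtained by
  substituting the closure into the exact unclosed equations. Its validity
  is certified against the independently specified planar fast system: at
  `N = 1e6` the full system's early-time `d(alpha)/dt` converges to the
  fast system's as `I0 -> 0` (tested at `I0` in {1, 0.1, 0.01}), and the
  relaxed fast variables match the steady-state cubic across the study
  grid.
* **Pair-level conservation for the compact improved closure.** The
  clustered part self-normalises over `{S, I}`; the conservation identity
  `sum_A [ASI] = (n-1)[SI]` therefore holds over `{S, I, R}` with the
  R-triple closed by its unclustered part only. This is how the identity is
  tested.
* **Plateau measurement.** "The fast variables plateau at the
  quasi-equilibrium" is operationalised as: the trajectory value at the
  point of slowest change (smallest finite-difference step) between the end
  of the initial transient and the prevalence peak matches
  `quasi_equilibrium()` to 1%. A fixed time window would conflate the
  transient tail with the plateau.
* **Threshold vs final size.** The correspondence between the `R = 1`
  crossing in `tau` and the rise of the attack rate is quantified by
  comparing the bisection root of `R(tau) = 1` with the `tau` at which the
  attack rate crosses the 1% classification level. With `I0/N = 1e-4` the
  subcritical attack rate behaves like `(I0/N)/(1 - R0)`, so the 1% level
  sits at `1 - R0 ~ 0.01`, a `tau`-offset of roughly 0.005-0.011 at the
  reference parameters; the transition has a genuine, parameter-dependent
  width and is not a step.
* **Expansion accuracy windows.** At `n = 5`, `tau = gamma = 1` the
  first-order (in `phi`) root error grows from 0.15% at `phi = 0.05` to
  ~7% at `phi = 0.3` for the simple closure, and is smaller at every
  `phi` for the compact improved closure (~4% at 0.3, ~10% at 0.45); the
  acceptance script recomputes these percentages. The truncation is
  strictly first order — no second-order coefficients exist in the
  analysis — and the series is never evaluated beyond `phi = 1`.
* **Edge-list dialect.** Whitespace-separated integer pairs, one undirected
  edge per line, 0- or 1-based, duplicates and self-loops rejected: the
  simplest unambiguous format.
* **Interfaces.** The command-line tool `exec/pairwise-sir` is a thin
  wrapper over the exported functions (subcommands `threshold`, `sweep`,
  `contour`, `timecourse`, `phaseplane`, `clustering`); `--config` accepts
  YAML or JSON and explicit flags override it; CSV outputs carry a JSON
  metadata sidecar.

## Problem sizes

The default test-suite and acceptance runs use: the full study grid above
(~400 parameter points) for cubic-vs-relaxation agreement; 50 random
parameter draws for the correlation-equation equivalence; 100 random draws
for the motif/percolation first-order identity; trajectories of 501 output
points on `[0, 1000]`; and graphs of at most 8 nodes for the brute-force
clustering oracle. These sizes were chosen so that every equivalence is
exercised across its whole feasible range while a complete run stays
interactive.

## Known limitations

* Regular networks only; the degree-heterogeneous extension is out of
  scope, as are SIS/SEIR dynamics and weighted, directed or adaptive
  networks.
* No explicit stochastic (Gillespie) network simulation: thresholds are
  validated against the models' own cubic/ODE/NGM routes, not against
  simulated epidemics.
* The four-dimensional fast system of the full improved closure is not
  implemented; the full improved closure itself is exposed only for
  conservation checking.
* The NGM construction uses the simple-closure quasi-equilibrium; a
  compact-improved NGM is not derived.
* Global stability of the fast subsystem's steady state is certified only
  within the proven Bendixson bound; `stability_conditions()` reports the
  flags honestly and makes no claim outside them.
* The household comparison is fixed at household size three with a regular
  global degree.
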