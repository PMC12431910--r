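---
title: "Replicator dynamics on networks: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator dynamics on networks: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replinet)
```

# The model

`replinet` simulates a metapopulation of habitats ("nodes") connected by a
network.  Within node $i$, the frequencies $x^i \in S_n$ of $n$ species (or
strategies) evolve under the replicator equation for a payoff matrix $A^i$:

$$\dot x^i_k = x^i_k\left[(A^i x^i)_k - (x^i)^\top A^i x^i\right] + T_k(x^i)(t).$$

Each species grows at a rate equal to its fitness advantage over the node's
average fitness; the state space of a node is the probability simplex $S_n$.
The coupling term $T$ exchanges density between adjacent nodes in one of two
forms:

* **linear transport** with a transfer velocity $\nu \ge 0$ per edge,
  $T^\nu_k = \sum_{j \in c(i)} \nu_{ij}\,(x^j_k(t) - x^i_k(t))$ — diffusive
  relaxation of inter-node differences;
* **delayed transport** with a per-edge survival rate $p$ (per unit time) and
  travel time $\tau$, where the exchange is attenuated by the survival
  probability $e^{-p\tau}$ of the journey and involves states one travel
  time in the past.

$c(i)$ is the neighbor set of node $i$.  On directed networks the package
defaults to the *incoming-flow* convention: an arc $j \to i$ makes $j$'s
state enter $i$'s balance.  The opposite convention is available behind
`network_graph(..., direction = "out")`; the choice matters for the oriented
prototype networks, where the in-convention reproduces the expected
asymmetry between otherwise symmetric nodes.

## The delayed form and its two variants

The delayed exchange is implemented in two variants:

* `formulation = "printed"`:
  $e^{-p\tau}\,(x^j(t) - x^i(t-\tau))$ — the neighbor's current state
  against the node's own delayed state;
* `formulation = "departure"`:
  $e^{-p\tau}\,(x^j(t-\tau) - x^i(t))$ — arrivals that departed the
  neighbor one travel time ago, relaxing the node's current state.

Both conserve each node's total density when all states lie on the simplex,
but they behave very differently on the unit interval.  The "printed"
variant couples quantities at different times with the wrong relative sign
to act as a relaxation: in the benchmark roundabout experiment it steadily
pumps amplitude until coordinates leave $[0,1]$ (values near $-3$ and $+4$
by $t \approx 70$).  The "departure" variant is a genuine delayed
relaxation: trajectories stay inside the simplex and the ensemble
synchronizes onto a common cyclic orbit, which is the phenomenon the
delayed-transport benchmark is about.  For this reason
`preset_test2_nonlinear()` uses `"departure"` by default, while
`transport_spec()` keeps `"printed"` available for sensitivity checks.

Delay systems need an initial *function*, not just an initial value; the
package uses the constant pre-history $x^i(t) = x^i(0)$ for $t \le 0$.

## Equilibria and stability

For a single node, interior equilibria solve the equal-fitness linear
system $(Ax)_k = x^\top A x$ together with $\sum_k x_k = 1$
(`interior_equilibrium()`; singular systems with a solution manifold are
reported as `"degenerate"` rather than silently absent).  Classification
uses three nested notions:

* **fixed point**: the replicator field vanishes;
* **Nash**: $x^{*\top}Ax^* \ge x^\top A x^*$ for all $x \in S_n$.  Because
  $x \mapsto x^\top A x^*$ is linear over the simplex, the maximum sits at a
  vertex, so `is_nash()` is an exact finite check;
* **ESS**: $x^{*\top}Ax > x^\top A x$ for all nearby $x \ne x^*$.  For two
  species `is_ess()` is exact (sign analysis of a quadratic in one
  variable via the diagonal reduction $a' = a - c$, $b' = d - b$); for
  $n \ge 3$ no finite certificate is available, so the condition is checked
  on seeded random simplex points within a radius of $x^*$ (defaults:
  radius 0.1, 200 samples).  The radius default is a choice, not derived:
  the ESS neighborhood is not quantified in general.

For the coupled system with linear transport, a relative-entropy Lyapunov
function $V(x) = -\sum_i \sum_k x^*_k \ln(x^i_k/x^*_k)$ certifies
asymptotic stability of a shared ESS $x^*$ when every node's margin
$x^{*\top}Ax^i - x^{i\top}Ax^i - \nu\,|c(i)|$ is positive
(`transport_stability_margins()`).  A network-level sufficient condition is
$\nu < 1/\Delta$ with $\Delta$ the maximum degree (`stability_bound()`):
$1/2$ for the chain and the triangle, $1/3$ for the six-node roundabout.
Note the margin condition fails *identically at* $x^i = x^*$ (the first two
terms cancel); it is meaningful on a punctured neighborhood, and the
package evaluates it literally.

Simplex invariance of the coupled flow is a structural property — the
replicator term's components sum to zero, and so do the linear-transport
rows when all nodes are on the simplex — so the integrator *monitors* the
row sums rather than renormalizing: a guard aborts when the deviation
exceeds `guard_tol` (default $10^{-6}$), signalling a step size problem
instead of hiding it by projection.  Positivity is monitored but not
enforced; coupled dynamics can legitimately re-awaken locally extinct
species, and the delayed variants are not guaranteed to preserve
positivity at all.

# The integrator

The march is the two-stage Gauss–Legendre implicit Runge–Kutta method
(order 4, A-stable, symplectic), solved per step in predictor–corrector
form:

1. two explicit-Euler predictors at the Gauss abscissae
   $c_{1,2} = \tfrac12 \mp \tfrac{\sqrt3}{6}$;
2. fixed-point iteration of the stage equations
   $k_i = f(t_n + c_i\Delta t,\; y_n + \Delta t \sum_j a_{ij} k_j)$,
   stopped when $\max(\|k_1 - k_1^C\|_2, \|k_2 - k_2^C\|_2) < \varepsilon$;
3. update $y_{n+1} = y_n + \tfrac{\Delta t}{2}(k_1 + k_2)$.

Design choices worth knowing:

* **Corrector.** Functional iteration contracts when $\Delta t\,L < 1$; all
  benchmark runs use $\Delta t \le 0.1$ on bounded payoffs, where a handful
  of sweeps suffice.  The residual norm is the Euclidean norm over all
  $N \times n$ components.  Defaults $\varepsilon = 10^{-12}$ and 50
  iterations: the convergence studies resolve errors near $10^{-13}$, which
  requires stage residuals below that scale.  The reference R
  implementation `pec_step()` adds a simplified-Newton fallback (frozen
  finite-difference Jacobian) for stiff probes such as $\dot y = \lambda y$
  with $\lambda \Delta t = -100$, where fixed-point iteration cannot
  contract; the compiled model march has no need for it.  The number of
  corrector sweeps is therefore not fixed a priori — iteration runs to
  tolerance — and the per-run statistics are reported in the trajectory's
  `meta`.
* **Dense output and delays.**  Accepted steps store the state and the
  right-hand side; delay lookups use cubic Hermite interpolation on the
  bracketing step, which is exact for cubics and locally $O(\Delta t^4)$ —
  matched to the scheme's order so history lookups do not degrade the
  observed convergence.  Lookups at stage times that fall beyond the newest
  accepted point extend the last closed segment's cubic; predictor states
  are never inserted into the history.
* **No adaptivity.**  All experiments are fixed-step ($\Delta t = 0.01$
  unless stated); the trajectory grid is uniform, which the error norms and
  event detectors rely on.
* **Baselines.**  First-order explicit and implicit Euler steps share the
  same right-hand side and are used for the long-run conservation
  comparison: on the cyclic three-species game the quantity
  $\sum_k \frac13 \ln x_k$ is conserved by the exact flow; explicit Euler
  spirals outward (the invariant decreases), implicit Euler damps inward
  (it increases), while the Gauss–Legendre scheme holds it to below
  $10^{-6}$ over $t \in [0, 100]$ at $\Delta t = 0.01$.
* **Compiled core.**  The production march (`integrate_model()`) is C++;
  `pec_step()` is the readable R reference, and the test suite asserts the
  two agree to near machine precision on coupled runs.  An adaptive
  general-purpose solver (deSolve) serves as an independent cross-check in
  the tests for both the smooth and the delayed system; it is never the
  implementation.

# Post-processing

* **Error norms.**  Convergence studies compare each run against a
  fine-grid run of the same scheme on a nested grid at the coarse run's
  stored times.  The discrete $L_2$ norm is time-weighted,
  $\sqrt{\Delta t \sum (\cdot)^2}$; $L_\infty$ is the max over all nodes,
  species and times.  Because no discrete-norm convention is universal,
  raw error magnitudes are not comparable across implementations — the
  experimental orders of convergence (EOC,
  $\ln(e_{i-1}/e_i)/\ln(\Delta t_{i-1}/\Delta t_i)$) are, being invariant
  to any common rescaling of the errors, and they are what the package's
  acceptance checks pin down.
* **Equilibration time.**  The earliest stored time after which every node
  stays within `tol` (max norm) of the target for the rest of the horizon
  (a trailing-window criterion, so transient crossings do not count).  The
  default `tol = 1e-3` is a calibration: near a mixed ESS of the two-species
  benchmark game the reduced dynamics contract like $e^{-t}$, and the
  $10^{-3}$ threshold makes the reported time coincide with the moment
  trajectories become visually indistinguishable from the equilibrium on a
  plot — with `tol = 0.01` every reported time would simply shift earlier
  by $\ln 10 \approx 2.3$ time units.
* **Synchronization time.**  Same trailing-window idea on the largest
  inter-node spread (max over species of the node-wise range); default
  `tol = 1e-3`, with $10^{-2}$ the sensible scale when comparing against
  visually-read synchronization onsets.
* **Ternary coordinates.**  Three-species trajectories map to the plane by
  $(x_1 + \tfrac12 x_2,\; \tfrac{\sqrt3}{2} x_2)$, sending the simplex to
  an equilateral triangle for plotting.

# Benchmark presets and the synthetic generator

The presets encode the benchmark study conditions:

* `preset_test1()` — one node, the cyclic rock–paper–scissors game
  (skew-symmetric payoffs), $\Delta t = 0.01$, horizon $T = 100$, four
  pinned initial conditions including the mixed equilibrium.
* `preset_test2_linear()` — hawk–dove variant (two species) or RPS (three
  species) on the chain / triangle / roundabout and their oriented
  variants; node 1 starts at the mixed equilibrium, all others at a pure
  state.  Horizons: $T = 20$ (two species; every equilibration event of
  interest ends by $t \approx 8$) and $T = 200$ (three species, long enough
  to distinguish equilibration from orbit formation).  Velocities at or
  above $1/\Delta$ are accepted with a warning — that regime is explored
  deliberately.
* `preset_test2_nonlinear()` — roundabout with delayed transport, $p = 2$
  on every edge, stub travel time $\tau^1$ (edges 1–2 and 5–6) and
  quadrangle travel time $\tau^2$ (edges 2–3, 3–5, 5–4, 4–2); node 1 at
  the mixed equilibrium, nodes 2–6 drawn uniformly (flat Dirichlet) on the
  simplex under a caller-supplied seed.  Horizon $T = 200$, covering the
  synchronization window with margin.

The random generators (`random_payoff()`: i.i.d. centered normal entries
with a scale parameter — a conventional random-matrix choice, as no
particular law is canonical; `random_simplex_point()`: flat Dirichlet) are
deterministic under a seed and leave the session RNG stream untouched.

What the synthetic conditions do *not* emulate: measurement noise,
demographic stochasticity, births/deaths outside the replicator term,
density-dependent or stochastic migration, and any real ecological data.
Passing the benchmark suite shows the deterministic model and its
integrator behave as designed, not that the model fits any particular
ecosystem.

# Numerical edge cases

* Simplex membership checks use tolerance $10^{-9}$ by default; fixed-step
  $O(\Delta t^4)$ drift at $\Delta t \le 0.01$ stays orders of magnitude
  below this.
* `interior_equilibrium()` distinguishes inconsistent equal-fitness systems
  (`"absent"`) from singular ones with a solution manifold
  (`"degenerate"`) via an SVD rank test and a least-squares residual.
* Zero `scale` in `random_payoff()` degenerates to the zero matrix (useful
  for isolating the transport operator in tests).
* A corrector that cannot reach tolerance raises an error naming the final
  residual — the remedy is a smaller step, never a silent acceptance.

# Known limitations

* The sampled ESS check for $n \ge 3$ is probabilistic: it can accept a
  non-ESS whose violations hide from the sample.  The two-species branch is
  exact.
* Event times (equilibration, synchronization) are resolved to the stored
  grid and depend on their tolerance; both are reported alongside the
  value.
* The delayed system's convergence order can in principle be limited by the
  cubic Hermite history (local $O(\Delta t^4)$) when delays interact with
  discontinuity propagation; the benchmark configurations show no such
  degradation.
* Orbit formation above the stability bound ($\nu \ge 1/2$ in the
  three-species networks) is reproduced qualitatively; the package does not
  analyze whether it is a genuine bifurcation or a slow transient.
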