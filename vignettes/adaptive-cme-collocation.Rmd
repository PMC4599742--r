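---
title: "Adaptive Gaussian collocation for chemical master equations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Gaussian collocation for chemical master equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rbfCME)
```

## The problem

A well-mixed reaction network with $d$ species and $K$ channels defines a
Markov jump process on the copy-number lattice $\Omega = \mathbb{N}^d$. The
probability $u(x,t)$ of holding exactly $x$ copies obeys the chemical master
equation (CME)

$$\frac{\partial u}{\partial t} = \mathcal{L}u, \qquad
(\mathcal{L}u)(x) = \sum_{i=1}^{K} a_i(x-\nu_i)\,u(x-\nu_i) - a_i(x)\,u(x),$$

with propensities $a_i(x) \ge 0$ and stoichiometric vectors $\nu_i \in
\mathbb{Z}^d$. Using per-axis shift operators $T_k$ and multiplicative
operators $W_a : u \mapsto a\cdot u$, the generator factorises as
$\mathcal{L} = \sum_i \left(\prod_k T_k^{\nu_{ik}} - I\right) W_{a_i}$, which
is the form every solver in this package discretises.

Even after truncation to a box the state count is punishing: the classical
two-gene toggle switch on $[0,300]^2$ has $90601$ states. Yet at any moment
almost all probability sits on a small, moving, possibly multi-component
subset — the *essential support*
$\operatorname{esupp}(u) = \{x : u(x) > p_{\mathrm{threshold}}\}$. The
package's central solver parametrises the solution only there.

## The collocation scheme

Each basis centre $x^j$ (drawn from a coarse candidate grid of spacing $h$)
carries an anisotropic Gaussian
$\phi_j(x) = \prod_k \exp(-(x_k - x^j_k)^2/\sigma_{jk})$, and the solution is
sought as $\tilde u = \sum_j \alpha_j \phi_j$. With the interpolation matrix
$A_{ij} = \phi_j(x^i)$ the coefficient-space operators are

* shift: $\tilde T_k = A^{-1} A_1$ with $(A_1)_{ij} = \phi_j(x^i - e_k)$,
  higher powers by composition;
* multiplication: $\tilde W_a = A^{-1}\operatorname{diag}\{a(x^j)\}A$;
* generator: $\tilde{\mathcal L} = \sum_i (\prod_k \tilde
  T_k^{\nu_{ik}} - I)\tilde W_{a_i}$, stepped by
  $\alpha(t+\Delta t) = e^{\Delta t \tilde{\mathcal L}}\,\alpha(t)$.

A note on operator ordering: composing in coefficient space requires
$\tilde T_k = A^{-1}A_1$ — the variant $A^{-1}A_1A$ sometimes written in the
literature maps nodal values, not coefficients, and would double-apply $A$
inside the generator product. Both readings coincide at the nodes in the
interpolatory limit; the package uses the coefficient-space form, which makes
the generator product self-consistent and, as the test suite verifies,
renders every *interior* row of the nodal operator $A\tilde{\mathcal L}A^{-1}$
exactly equal to the sparse generator when the centres cover all box states.
Only the boundary rows differ: the collocation interpolant extrapolates
across the box edge where the conserving truncation of the exact generator
zero-fills, a defect that decays geometrically into the interior with the
off-diagonal decay rate of $A^{-1}$.

The shape parameter is set per centre as $\sigma = (c\,h)^2$ with $c = 1.2$
by default. This was chosen once, from the measured trade-off on the study
initial conditions: at $c = 1.2$ the interpolation error of a smooth
lattice Gaussian is two orders of magnitude below the $c = 0.85$ value while
the 1-norm condition estimate of $A$ stays in the $10^2$–$10^4$ range for
the basis sizes the solver uses (hundreds, occasionally a couple of
thousand), far below the configurable failure cap of $10^8$. The condition
estimate is computed at construction from the already-available inverse
($\|A\|_1\|A^{-1}\|_1$), so it is essentially free.

## Support geometry

All geometry lives on the candidate-centre grid, with distances in units of
one grid step.

* The **alpha-region** of a lattice set is its morphological closing with a
  Euclidean ball of radius $\alpha$ (dilation then erosion, both via exact
  distance transforms). This is a deliberate lattice approximation of the
  alpha-hull: it preserves holes and disjoint clusters at small $\alpha$,
  fills them as $\alpha$ grows, and keeps every operation on the fixed
  Cartesian grid. The default $\alpha = 2$ grid steps is the conventional
  choice (one grid step is the lower bound).
* The **signed distance field** is negative inside the alpha-region and
  positive outside, with exact Euclidean lattice distances on both sides
  (a Felzenszwalb–Huttenlocher transform per axis, dimension-agnostic).
  The zero sublevel set recovers the alpha-region exactly; offsetting the
  level by $\gamma$ inflates it, and the pointwise minimum of two fields
  represents the union of their regions.
* The support at the next step is **extrapolated** by advancing the signed
  distance field linearly in time (the finite-difference form of the
  level-set transport equation). This is exact for rigid translation at
  constant speed — flat fronts extrapolate perfectly, curved fronts to
  within one cell per step — and the test suite pins both properties down.
  The predicted displacement is capped at $\gamma + \alpha$ grid units per
  step: the speed estimate divides a possibly noisy one-cell boundary
  flicker by the previous interval length, and an uncapped prediction can
  balloon the candidate region by orders of magnitude when the intervals
  are short.

## The adaptive loop

1. **Initialise.** Normalise $u_0$, take its essential support on the
   candidate grid, inflate the alpha-hull by $\gamma$, place one Gaussian on
   every grid point of the inflated region, and interpolate. If the
   interpolant misses $u_0$ by more than $p_{\mathrm{threshold}}$ anywhere
   on the fine lattice near the support, the grid is halved (twice at most)
   before giving up.
2. **Predict.** Extrapolate the support to $t + \Delta t$ (the first step
   integrates on the initial support — no history exists yet).
3. **Step.** Build the basis on the inflated hull of (current support
   $\cup$ prediction), transfer coefficients by evaluating the old
   interpolant at the new centres, and advance with the Krylov exponential.
4. **Validate.** Recompute the essential support of the stepped interpolant
   and measure its signed-distance discrepancy to the prediction (sup-norm
   over the union of the two alpha-regions); also compare the total mass of
   the interpolant (integrated over the integer lattice with per-kernel
   truncation) against the initial mass. A step is accepted when the
   discrepancy is within `supportTol` **or** the computed support stayed
   strictly inside the $\gamma$-inflated basis region (see below), **and**
   the mass deviation $(\sum u_0 - \sum u)/\sum u_0$ is within `massTol`.
   Otherwise the step length shrinks by `dtShrink`; if the mass check keeps
   failing after three rejections the threshold is halved, as a lower
   threshold is the only cure for genuine probability loss through the
   support boundary.

Three policies here deserve their rationale:

* **Step regrowth.** After a clean acceptance the step returns to `dtInit`;
  after a rejected-then-accepted step it only doubles. The level-set speed
  is estimated from the last two accepted intervals, so consecutive
  intervals must stay comparable; jumping from a collapsed step straight
  back to `dtInit` amplifies boundary noise by the interval ratio and was
  observed to balloon the prediction catastrophically.
* **Containment acceptance.** A probability shoulder that crosses the
  threshold tangentially moves the support boundary discontinuously — no
  finite-difference prediction can match it, and no step length makes the
  discrepancy small, so the raw validation rule deadlocks with the step
  collapsing to zero. The escape hatch is sound: if the computed support
  never left the strict interior of the basis region, the solution was
  never clipped and only the *prediction* was conservative, so the step is
  accepted and the next prediction restarts from the enlarged support. If
  the step cannot be accepted on any grounds the solver still stops with an
  actionable error once the step has collapsed nine decades below `dtInit`.
* **Validation noise floor.** A single rim cell appearing or disappearing
  moves the closed boundary by up to $2\sqrt{2}$ grid units under
  $\alpha = 2$ closing, so `supportTol` below $\approx 3$ rejects pure
  flicker. The package default keeps the conventional 2 grid units; the
  bundled studies run at 3.

**What the threshold costs.** Truncating at $p_{\mathrm{threshold}}$
abandons the probability that lives below it: the sub-threshold mass of the
target distribution is a floor on the achievable accuracy, and the support
edge keeps leaking at a rate roughly proportional to the threshold. The
toggle-switch convergence study in the acceptance suite shows exactly the
expected picture — relative $\ell_2$ error against the exact stationary
solution decreasing as the threshold drops through $10^{-5}, 3\cdot10^{-6},
10^{-6}$ at fixed grid spacing, flattening toward the common
time-truncation floor ("fixed $n$" is realised as fixed candidate-grid
density; the active basis size then varies with the threshold, as it must
in a support-adaptive scheme). Conversely the topology study deliberately
uses a coarse threshold above the inter-mode saddle so the support splits
into two components and the degrees of freedom fall — there the mass drain
is substantial and accepted, which is why `massTol` is wide in that run;
quantitative work should use thresholds well below the saddle.

## Full-state solver

The reference solver assembles the sparse generator with **conserving
truncation**: any channel whose target state leaves the box contributes no
flux, so every column sums to zero exactly and mass is conserved on the box
(the alternative, absorbing truncation, would make the mass-deviation
safeguard of the adaptive solver meaningless).

* **Stationary distributions** are computed by a direct sparse null-space
  solve: pin one unknown, solve, renormalise; then re-solve pinned at the
  distribution mode so the deep tail is not polluted by cancellation
  against a pinned tail state (the truncated birth–death chain then matches
  the closed-form truncated Poisson to $10^{-10}$ *relative* error, tail
  included). An outflow-free state, if present, is pinned first — it is
  both the only safe pin and the location of the stationary mass.
* For **permutation-equivariant networks** (the symmetric tristable switch)
  the solve can be restricted to the orbits of the axis-permutation group:
  with $R$ summing states over orbits and $E$ spreading orbit mass
  uniformly, the orbit generator $R\mathcal{L}E$ has one unknown per orbit
  (a six-fold saving in 3-D) and its null vector expands to the full
  stationary distribution. The result is validated against the *full*
  generator's residual, which certifies it independently of the symmetry
  assumption, because the stationary vector of an irreducible chain is
  unique. This matters because sparse LU of a 3-D stencil beyond $10^5$
  states is impractical, and long-time integration is untrustworthy for
  metastable systems — it returns whichever quasi-stationary state the
  initial condition selects, with a deceptively small residual.
* **Transients** use uniformization: the Poisson-weighted power series of
  $P = I + \mathcal{L}/\lambda$, $\lambda = \max_i |\mathcal{L}_{ii}|$,
  summed over substeps with the Poisson mean capped at 500 and the series
  truncated at $10^{-12}$ tail mass. The matrix exponential is never
  formed. The collocation operator is not a generator (its spectrum carries
  discretisation artefacts), so the coefficient step instead uses an
  Arnoldi/Krylov approximation of the exponential action with adaptive
  substepping; both routes are cross-checked in the tests against a stiff
  ODE solve (`deSolve::lsoda`) and against a dense Padé exponential.

## Built-in models

* **Bistable toggle switch** (2 species, 4 channels): Hill-repressed
  production $a_1 = c_1/(c_2 + y^\beta)$, $a_3 = c_4/(c_5 + x^\gamma)$ and
  linear decay, with the classical constants $c_1 = c_4 = 3\cdot10^3$,
  $c_2 = c_5 = 1.1\cdot10^4$, $c_3 = c_6 = 10^{-3}$, $\beta = \gamma = 2$.
  The stationary solution on $[0,300]^2$ is bimodal with modes near
  $(223, 49)$/$(49, 223)$ and an inter-mode saddle at about 2% of the
  maximum — so a support that separates the modes needs a threshold
  *above* that saddle, and 1% of the maximum gives a single connected
  (though still small: ~13% of the box) support.
* **Tristable switch** (3 species, 6 channels): each species is repressed
  by the *sum* of its two competitors, $a_1 = c_1/(c_2 + (y+z)^\beta)$ etc.
  A caution discovered while building the reduced test system: with the sum
  coupling, corner fixed points exist only while the Hill half-point
  $\sqrt{c_2}$ is much smaller than the corner coordinate
  $c_1/(c_2 c_3)$. Scaling all constants proportionally (keeping the
  original's ratio) destroys the corner attractors — the fixed-point
  iteration collapses onto the symmetric central state, which is linearly
  stable for this model family and then dominates the exact stationary
  distribution. `tristableParamsReduced()` therefore sharpens the
  repression instead ($c_1 = 4.4$, $c_2 = 16$, $c_3 = 10^{-2}$): the
  asymmetric modes sit at $(27, 0, 0)$ and permutations, the central state
  is 40-fold weaker, and a full-grid box of $[0,45]^3$ suffices — this is
  the configuration the acceptance suite solves exactly via the orbit
  reduction. At full scale the corner states are deep metastable traps, so
  a time-stepping run started near the origin exhibits the trimodal
  configuration essentially forever even where the exact null vector
  favours the centre.
* **Osteochondral switch** (OCS): the stem-cell differentiation network
  with asymmetric Hill propensities for osteogenic, chondrogenic and
  progenitor factors; the published parameter table is the default,
  `mp = 8` switches it from bistable to tristable, and a pro-osteogenic
  stimulus `zo` adds to the basal osteogenic activity only.
* **Self-regulating gene**: a pair of coupled one-dimensional master
  equations for the free/repressed promoter — not a CME (the switching
  terms are multiplicative), represented here on a doubled lattice
  $(x, g)$, $g \in \{\text{on}, \text{off}\}$ so the same machinery
  applies. Two printed forms of the switching terms circulate, differing
  in sign in the repressed-state equation; only one conserves probability
  against the free-state equation, and the package implements that
  orientation (every assembled column sums to zero — the package treats
  column-sum conservation as non-negotiable). The bound state requires at
  least one protein; degradation of the last free protein in the bound
  state re-opens the promoter, $(1,\text{off}) \to (0,\text{on})$, making
  $(0,\text{off})$ unreachable. Binding does not change the protein count
  (the monomer/dimer distinction enters only through the rate law
  $h(x) = hx$ versus $h(x) = \tfrac{h}{2}x(x-1)$), mirroring how the model
  is conventionally written.

## SSA baseline

The Gillespie simulator is table-driven: propensities are precomputed on
the truncation box with exactly the generator's zero-outgoing-flux
convention, so the simulated chain *is* the truncated-generator chain and
occupancy estimates are directly comparable with `steadyState()`. Occupancy
is waiting-time weighted by default (the ergodic estimator; a visit-count
mode exists for comparison), accumulated exactly over every step even when
the stored trajectory is thinned. For a bistable system the occupancy error
after a finite run is dominated by the imbalance of time spent per mode,
which puts a hard ceiling on how bad the estimate can be: a trajectory that
never switches at all has error exactly $\|u_{ss}\|_2$ (restricting to one
mode doubles it there and zeroes the other, and the two contributions each
integrate to $\tfrac12\|u_{ss}\|_2^2$ by symmetry). The acceptance suite
measures where 10-million-step trajectories actually land relative to the
published comparison.

## Problem sizes and runtimes in the shipped tests

The unit tests run on chains of 10–70 states, 2-D boxes up to $51^2$ and
3-D boxes up to $7^3$; property checks loop over fixed-seed random masks
and states. The acceptance suite solves the full $90601$-state toggle
system exactly (seconds), the $97336$-state reduced tristable system via
its $17296$ orbits, three $10^7$-step SSA trajectories, and three adaptive
toggle runs to $t = 4\cdot10^4$ plus one splitting run to $t = 3\cdot10^4$
on a 6-step candidate grid (a few hundred basis functions against 90601
states). These sizes were chosen as the smallest that still exercise every
mechanism at study scale.

## Known limitations

* Basis centres are confined to a fixed candidate grid; free-form centre
  placement is out of scope.
* The collocation operator does not conserve mass by construction; the
  mass check monitors (and the threshold safeguard limits) the drift, but
  thresholds above the saddle of a multimodal target trade mass for
  support economy.
* Dimensions beyond 4 are out of reach of the dense interpolation-matrix
  factorisation.
* The validation metric inherits a discrete noise floor from single-cell
  support flicker; `supportTol` below ~3 grid units (at $\alpha = 2$) will
  reject legitimate steps.
* Stationary solves rely on a single closed communicating class inside the
  box (a reducible chain with several closed classes has no unique
  stationary vector to find).
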