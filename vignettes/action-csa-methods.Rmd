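---
title: "Finding multiple transition pathways by global action optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding multiple transition pathways by global action optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actioncsa)
```

## The problem

Given two metastable configurations of a system that evolves by overdamped
Langevin dynamics,

$$\gamma \dot{x} = -\nabla V(x) + R(t), \qquad
\langle R(t) R(t')\rangle = 2\gamma k_B T\, \delta(t - t'),$$

we want *all* the plausible reaction routes connecting them, together with
their relative importance — not just the single route nearest to an initial
guess. Local chain-of-states schemes (elastic bands, string methods) refine
one pathway; unbiased simulation finds routes in proportion to their rates
but needs prohibitively long trajectories when barriers are high. This
package treats the task as global optimization over pathway space: a pathway
is a chain of $P+1$ replicas $x_0 \dots x_P$ separated by a time step
$\Delta t$ with both endpoints fixed, and the search is a genetic algorithm
(conformational space annealing, CSA) over whole chains.

## Actions

**Scoring.** The probability of observing a diffusive path is proportional
to $e^{-S_{OM}/k_B T}$ with the Onsager–Machlup (OM) action. In its
generalized form,

$$S_{OM}[x] = \frac{\Delta V}{2}
 + \int_0^t \left[\frac{\gamma}{4}\lvert\dot x\rvert^2
 + \frac{\lvert\nabla V\rvert^2}{4\gamma}
 - \frac{k_B T}{2\gamma}\,\mathrm{tr}\,\nabla^2 V\right] dt',$$

where $\Delta V = V(x_f) - V(x_i)$. The trace-of-Hessian term is the
entropic correction describing the width of the tube of trajectories around
a path. Minimizing this form directly would require third derivatives of
$V$, so the search instead scores pathways with the *symmetric* OM formula
— the same expression without the entropic term, which needs only
gradients — discretized to second order with trapezoidal weights:

$$S_{OM} \approx \frac{\Delta V}{2}
 + \sum_{j=0}^{P-1}\frac{\gamma\,\lvert x_{j+1}-x_j\rvert^2}{4\Delta t}
 + \frac{\Delta t}{4\gamma}\sum_{j=0}^{P} w_j \lvert\nabla V(x_j)\rvert^2,
 \qquad w = (\tfrac12, 1, \dots, 1, \tfrac12).$$

`om_action()` implements this sum; `om_action_continuous()` is a fine
quadrature of the continuous integral along the piecewise-linear chain,
kept as a testing oracle (with the entropic term switchable, and verified
against its closed form $-k_B T\,\mathrm{tr}H\,t/2\gamma$ on the harmonic
well, where the Hessian is constant). The discretization error of
`om_action()` against the entropic-free quadrature decays as
$O(\Delta t^2)$; a gradient-only sum evaluated on a smooth chain cannot
represent the trace term in more than one dimension, because gradients
sampled along a curve carry no information about curvature transverse to
it. Rankings in this package therefore compare symmetric-formula actions,
exactly as the one-point evaluation used inside the search.

**Local refinement.** Trial pathways produced by genetic operations carry
artifacts (kinks, duplicated replicas), which are removed by minimizing the
restrained classical action

$$\Theta = \mu_A S_{cl} + \mu_E \sum_{j=0}^{P-1}(E_j - E)^2, \qquad
S_{cl} = \sum_{j=0}^{P-1}\Delta t\left[
 \frac{\lvert x_{j+1}-x_j\rvert^2}{2\Delta t^2}
 - \frac{V_j + V_{j+1}}{2}\right],$$

with $\mu_A = -1$, $\mu_E = 1$: stationary paths of $S_{cl}$ are Newtonian
trajectories, the quadratic energy restraint selects among them the ones
that conserve total energy near the reference $E$, and minimizing $\Theta$
needs only first derivatives. Slice energies use forward-difference
velocities $v_j = (x_{j+1}-x_j)/\Delta t$, the same convention in
$S_{cl}$, in `replica_total_energy()` and in the penalty, which runs over
the $P$ slices; under this convention no one-sided boundary formula is
needed. The reference energy follows the equipartition rule
$E = V(x_i) + 3 N k_B T/2$ (`compute_reference_energy()`); for the toy
surfaces the *effective* atom count $N$ is chosen so that the kinetic
reference exceeds the highest barrier along admissible routes — with $E$
below the barrier tops no energy-conserving crossing exists and the
optimizer is forced into unphysical compromises, while an overly large $E$
merely makes transits fast. We use $N = 5$ on the two-channel surface
(kinetic reference 5.2 kcal/mol against barriers of 2.6 and 4.1) and
$N = 4$ on the two-dihedral chain (4.2 kcal/mol against a 3.9 kcal/mol
route summit, still far below the 8.9 kcal/mol cis summit).

`minimize_theta()` runs limited-memory quasi-Newton (L-BFGS-B) over the
$(P-1)\cdot d$ interior coordinates with the analytic gradient
(`theta_gradient()`, verified against finite differences), falling back to
backtracking gradient descent if the quasi-Newton step fails; it always
returns the best iterate seen, so $\Theta$ never increases and the
endpoints are never touched.

## The search

`action_csa()` follows the standard CSA loop adapted to pathways:

1. `generate_initial_paths()` draws random pathways: straight interpolation
   plus a mean-zero stochastic bridge of amplitude `init_scale`. For
   torsion coordinates each dihedral's winding direction is additionally
   randomized between the minimum-image rotation and the long way around —
   on a circle the two directions are distinct homotopy classes, and local
   minimization cannot move a chain between them, so an initializer that
   only takes the short way would never present the trans-side routes to
   the search.
2. Each initial pathway is Θ-minimized; the result is the immutable *first
   bank*. The *bank* starts as a copy of its best `bank_size` members (by
   default `n_initial = bank_size`, so the whole diverse first bank is
   copied; the bank-update rule below never admits a worse-but-new pathway,
   so diversity must be present from the start).
3. Each round, seed members are recombined by `crossover()` (one contiguous
   interior window copied from a partner drawn with equal probability from
   the bank or the first bank) or perturbed by `mutate()` (at most 5% of
   the interior degrees of freedom). Trials are Θ-minimized, their OM
   action is evaluated once, and `update_bank()` applies the two-branch
   rule: a candidate closer than $D_{cut}$ to its nearest bank member
   competes only with that member; otherwise it counts as a new pathway
   class and competes with the worst member. Ties keep the incumbent.
4. $D_{cut}$ starts at half the mean pairwise distance of the initial bank
   and anneals geometrically to a final fraction (`anneal_dcut()`), so the
   search is diversity-seeking early and refining late. Pathway distance is
   the discrete Fréchet distance (`frechet_distance()`), the minimax over
   monotone couplings of the replica sequences, with minimum-image angular
   metric in torsion space.
5. The run stops after `patience` rounds without improvement of the best or
   mean bank action (improvements smaller than $10^{-7}$ relative are
   ignored), or at `max_rounds`.

Identical seeds reproduce runs bit for bit.

## Toy surfaces

The shipped potentials stand in for molecular force fields at desk scale:

* `harmonic_well()` — exactly solvable reference.
* `muller_brown()` — the classic 2D benchmark.
* `two_channel_2d()` — Gaussian wells at $(\pm 1.14, 0)$ joined by two
  saddle channels around a central wall; the upper channel carries an
  extra bump so the barriers are 2.61 and 4.08 kcal/mol above the minima
  (gap 1.47 kcal/mol ≈ 2.1 $k_B T$ at 350 K, configurable via
  `barrier_gap`). Stationary points are located at construction-verifiable
  precision by `stationary_points()` (grid-scanned damped Newton).
* `torsional_chain(n)` — $n$ uncoupled dihedrals with a five-term cosine
  series placing exact minima at $\pm 60^\circ$ (gauche) and $180^\circ$
  (trans). Defaults: gauche 0.9 kcal/mol above trans, trans/gauche barrier
  3.0, cis barrier 8.0. The cis height matters: a route over one cis
  barrier costs total ascent $C - g$ while the trans route costs
  $(B-g) + B$, so cis routes are only disfavoured when $C > 2B - g$
  (here $8.0 > 5.1$). With the conventional alkane value of about 5.5 the
  one-barrier cis route would genuinely carry the lower action, and the
  no-cis assumption of the enumeration module would not describe this
  surrogate's dynamics.

All masses are unity; units are kcal/mol, ps, K, radians; $k_B = 0.0019872$
kcal mol$^{-1}$ K$^{-1}$; the thermodynamic defaults are $T = 350$ K and
$\gamma = 1$ ps$^{-1}$.

## Validation by direct simulation

`simulate_overdamped()` integrates the overdamped equation by
Euler–Maruyama (per-coordinate noise variance $2 k_B T \Delta t/\gamma$),
vectorized over an ensemble of walkers; its stationary statistics are
tested against the harmonic variance $k_B T/\kappa$ and the free-diffusion
law $\langle x^2 \rangle = 2 k_B T t / \gamma$. `detect_transitions()`
counts source→target events by the last-exit/first-entry convention
between disjoint basin cores, which filters dwell time out of the transit
time. Each transition segment is matched to a reference pathway by
resampled Fréchet distance (`assign_nearest_reference()`), and
`rank_order_comparison()` compares the frequency ranking with the action
ranking (Kendall's τ).

On `two_channel_2d()` at the default gap, a bank search at $t = 1.5$ ps
($P = 50$, $\Delta t = 30$ fs) finds both channels and assigns the lower
one the lower action (in a representative run, class minima 3.9 vs 6.5,
a gap of $\approx 2.6$ or a relative path weight of $e^{-2.6/k_B T}
\approx 0.02$ for the upper route; absolute actions vary between seeds
because $\Theta$ admits several locally optimal speed profiles per route,
but the class ordering is stable across all seeds tested). Ensembles of 64
walkers over 180 ps of simulation yield 100–130 transitions, of which
roughly three quarters take the lower channel. The transition time is a parameter of the search, not an output;
profiles of minimum action over total time (`som_vs_time_profile()`) are
U-shaped — fast paths pay kinetic cost, slow paths accumulate
gradient-squared cost — and the observed median transit time
($\approx 2$ ps) sits at or above the action-optimal time, as expected
when thermal dwell fluctuations are filtered out of the minimum-action
description.

## Torsional pathway enumeration

For the rotamer chain the complete set of transition routes from all-g⁻ to
all-g⁺ can be enumerated and used as ground truth for sampling
completeness. A pathway is a sequence of single barrier crossings, each
dihedral travelling g⁻→t→g⁺ (cis forbidden, each barrier crossed once, so
crossings are monotone), excluding intermediate chain states that put two
*adjacent* dihedrals in opposite gauche states — the steric clash familiar
from syn-pentane. For three dihedrals this gives exactly 44 pathways,
against 90 for unconstrained interleaving; brute-force graph search
reproduces the counts for $n \le 3$ in the tests.

`reduce_by_symmetry()` groups pathways into types under the mirror symmetry
of the dihedral potential (g⁻↔g⁺, which maps a pathway onto a
time-reversed one) and chain-order reversal (dihedral $i \mapsto n+1-i$).
Orbits alone give 15 classes for $n = 3$. One further identification is
applied by default (`merge_enclosed_concerted`): among the six sequences in
which the middle dihedral moves first and last, the four whose two outer
transits also overlap each other in time are a single concerted "crossed"
motif — simultaneous outer rotations enclosed by the middle rotation —
whose discrete interleaving order is not a mechanistically distinguishable
feature; they merge into one class, giving 14 types of sizes
$6\times2 + 8\times4 = 44$. The rule is vacuous for $n \le 2$ and touches
no other class (the enclosed-overlapping pattern occurs nowhere else), and
it is exposed as a scheme flag so the pure orbit partition remains
available.

`coverage_report()` closes the loop: each bank pathway's replica trace is
read off as a crossing sequence (`trace_events()`, basin boundaries at the
barrier angles) and matched against the enumeration; traces that re-cross
a barrier or cross cis are reported in a multi-crossing bin, and monotone
routes through clash states (which the *uncoupled* chain potential does
not penalize — the clash rule is an enumeration constraint, not a term of
this surrogate's energy) are listed as unmatched rather than dropped.

## Study conditions and problem sizes

The experiments reproduced by `scripts/acceptance.R` and the acceptance
tests use: two-channel rank order — bank 14, $P = 50$, $\Delta t = 30$ fs,
15 rounds, 10 independent seeds, each validated against 64 walkers ×
180 ps of Brownian dynamics; torsional coverage — chain of 2 dihedrals,
bank 20 from 36 initials, $P = 40$, $t = 3$ ps, 18 rounds, final
$D_{cut}$ at 6% of the initial mean pairwise distance (the four
interleavings of the two transits lie in one shallow valley of the
uncoupled chain, and a larger final cutoff merges geometrically close
interleavings into one bank slot), 10 seeds. These sizes were chosen once
as the smallest ensembles at which the two statistical outcomes are stable
across seed batches.

## Numerical choices and edge cases

* Torsion displacements are minimum-image everywhere (kinetic terms,
  Fréchet metric, bridge construction); angles live on $(-\pi, \pi]$.
* `resample_path()` is arc-length-uniform and endpoint-exact; resampled
  vertices lie exactly on the original polyline, whose Euclidean length it
  therefore approaches from below under refinement (any fixed-count
  resampling of a non-collinear polyline cuts corners, so exact length
  equality is reserved for collinear or vertex-aligned cases).
  `assign_nearest_reference()` skips resampling when replica counts
  already match, making self-assignment exact.
* Equal Fréchet distance to two references resolves to the lower index;
  bank ties at equal action keep the incumbent; a candidate at exactly
  $D_{cut}$ takes the neighbour branch.
* Degenerate trial pathways (coincident replicas) are legal optimizer
  input; removal of such artifacts is precisely the local minimization's
  job.
* `path_probability_ratio()` uses $e^{-\Delta S / c\,k_B T}$ with $c = 1$,
  the constant consistent with the package's action normalization;
  rankings never depend on $c$ and the constant is an argument.

## What the toy models do and do not show

Passing the suite demonstrates the machinery — correct functionals,
gradient-only scoring, diversity-preserving global search, simulation
cross-checks, complete enumeration — on smooth low-dimensional surfaces
with well-separated classes. It does not demonstrate force-field realism:
no molecular geometry, no solvent, no coupling between the surrogate
dihedrals (so interleaving classes are flat valleys rather than distinct
basins, a *harder* diversity test but an easier energetics test), and
Brownian rather than inertial dynamics. Wall-clock behaviour on
thousand-dimensional systems (where the method's per-trial cost is
dominated by force calls and parallelizes over trials) is likewise out of
scope here.
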