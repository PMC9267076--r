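---
title: "Methods: the bistable PrPC/amyloid loop model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bistable PrPC/amyloid loop model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bistaloop)
```

## The model and its assumptions

The package analyses a planar double-inhibitory feedback loop

$$\tau_A \dot A + A = g_A(P;s), \qquad \tau_P \dot P + P = g_P(A),$$

with decreasing Hill-type inhibition $g(x) = \gamma/(\delta^h + x^h)$.
$P$ stands for the pool of amyloid-β-oligomer-free cellular prion
protein (PrPC), which inhibits BACE1; $A$ lumps the whole amyloidogenic
axis — BACE1 activity, Aβ production, and oligomerisation — into one
activity that in turn depletes free PrPC by oligomer binding. The lumping
is the central modelling assumption: no mechanistic sub-model of APP
expression, BACE1 catalysis, oligomerisation kinetics or PrPC binding is
attempted; each agent simply relaxes with a first-order time constant
toward a monotone function of the other. Because the loop contains an
even number of inhibitions, it is a monotone positive-feedback system:
no oscillations are possible in the plane, and the only attractors are
equilibria. Everything is dimensionless and the time unit is set by the
relaxation constants, which default to 1.

## Stimulus coupling

The cyclic-nucleotide (cAMP/cGMP) input that promotes Aβ production is
a single scalar $s \ge 0$. Its biological action could be read either as
raising the maximal attainable amyloid activity or as weakening the
inhibition of the amyloid axis by PrPC, so both couplings are
implemented as modes of `loop_model()`:

* **gain** (default): effective $\gamma_A = s\,\gamma_A$. The simplest
  monotone coupling; $s = 0$ switches amyloid production off entirely,
  giving a clean decoupled limit used in tests.
* **threshold**: effective $\delta_A = \delta_A / \max(s, 10^{-9})$.
  The floor keeps the arm defined as $s \to 0$; below $10^{-9}$ the
  response is saturated anyway, so the floor has no visible effect at
  any stimulus of practical size.

cAMP and cGMP are not distinguished: the loop equations contain a single
input channel, and giving each nucleotide its own parameter would add a
dimension the planar model cannot constrain. Both Hill arms use the same
functional form; the inhibitions need not share a shape in principle,
but the decreasing Hill function is the canonical dose–response choice
and the two arms are parameterised independently, which is where the
asymmetry that matters lives. The Hill coefficient is any real
$h \ge 1$; $h < 1$ is rejected because it makes $g'$ unbounded at the
origin, which breaks the Jacobian contract.

## The canonical reference model

No published parameter values exist for this loop, so the package fixes
a canonical symmetric reference: $\gamma = 3$, $\delta = 1$, $h = 2$,
$\tau = 1$, $s = 1$ in gain mode. It was chosen because it is bistable
with fully closed-form structure: the stable equilibria are
$((3 \pm \sqrt 5)/2,\,(3 \mp \sqrt 5)/2)$ (from $1 + P^2 = 3P$), the
saddle is symmetric with $A$ solving $A^3 + A - 3 = 0$, and the stable
Jacobian eigenvalues are $-1 \pm 2/3$. Every structural claim the
package's tests make is anchored to these algebraic facts rather than to
the numerics being tested. Companion references are a subcritical
monostable model ($\gamma = 1$), the pitchfork threshold ($\gamma = 2$,
where $g'(1) = -1$ exactly and the symmetric point has a zero
eigenvalue), and a Hill-coefficient-1 model, which cannot be bistable:
its fixed-point equation is the quadratic
$\delta_A a^2 + (\delta_A\delta_P + \gamma_P - \gamma_A)a -
\gamma_A\delta_P = 0$, whose root product is negative, leaving exactly
one admissible equilibrium.

For symmetric models with $\delta = 1$, $h = 2$, the symmetric
equilibrium destabilises exactly at $\gamma = 2$: instability requires
$|g'(x^*)| > 1$ with $x^* = g(x^*)$, which reduces to $x^* > 1$, i.e.
$\gamma > 2$. This analytic threshold is verified numerically by a
$\gamma$-bisection in the tests.

## Equilibrium location: the one-dimensional reduction

Equilibria satisfy $A = g_A(g_P(A); s)$. The composition of two
decreasing bounded maps is increasing and bounded, so the residual
$F(a) = g_A(g_P(a)) - a$ is positive at 0, negative above
$\max g_A$, and crosses zero at every equilibrium. `find_equilibria()`
brackets sign changes of $F$ on a uniform grid over
$[0,\,1.05\max g_A]$ (default 2000 points), refines each bracket by
plain bisection to an interval width of $10^{-10}$, and removes
duplicates closer than $10^{-8}$. This is exhaustive for the monotone
loop structure and immune to the basin-dependent divergence of 2-D
Newton iterations. The known blind spot: two roots inside one grid cell
(possible only within $\sim 10^{-3}$ of a fold at the default grid) are
seen as one; near-fold work should raise `grid_n`. At an exact fold the
merged double root is reported once and classified `"marginal"`
(leading eigenvalue within $10^{-6}$ of zero — the same band used to
separate stable, saddle and unstable classes).

## Numerical integration

`integrate_loop()` and `run_to_steady_state()` wrap the adaptive LSODA /
LSODAR integrators with `rtol = 1e-8`, `atol = 1e-10` — loose enough to
keep thousands of basin-cell integrations fast, tight enough that
trajectories starting near the separatrix resolve the correct side.
States that step negative by less than `atol` are clipped to zero;
larger negativity is treated as an integrator fault rather than hidden.
Steady state is declared when the vector-field norm drops below
`tol = 1e-9` (LSODAR root-finding stops the integration exactly there,
within a default time budget of $10^4$). The criterion is deliberately
the field norm, not state displacement: near a saddle the state moves
slowly while the field is still appreciably nonzero, and a
displacement criterion would misread that transit as convergence.

## Bifurcation sweeps and hysteresis

`bifurcation_sweep()` re-solves the equilibrium problem on a stimulus
grid and bisects the stimulus between adjacent grid points where the
equilibrium count changes, to a tolerance of $10^{-6}$ — robust fold
detection that exploits the exhaustive 1-D root finder; pseudo-arclength
continuation would be the standard generalisation but is unnecessary for
a planar monotone system (noted as an extension point). Regimes are
labelled from stable-equilibrium counts; a single stable point is
`monostable_low` or `monostable_high` according to its $A$ relative to
the geometric mean of the invariant-box bounds, a scale-free midpoint.

`hysteresis()` operationalises "slow stimulus drift": at each of
`n_steps` stimulus values the system is re-settled from the previous
settled state, up then down. A jump is declared when settled $A$ moves
by more than 25% of the protocol's total $A$ range in one step; fold
crossings in this model class produce order-one jumps while drift along
a branch is orders of magnitude smaller, so the threshold is not
delicate. The reported jump stimulus is the grid value just after the
transition, hence within one step-width of the true fold — which is
exactly the consistency the tests assert against the sweep's folds, two
independent code paths.

## Basin maps

`basin_map()` integrates every cell of a uniform grid over the invariant
box to steady state and labels it by the stable equilibrium reached
(match tolerance $10^{-4}$, far looser than the $\sim 10^{-9}$ accuracy
of a converged state). Cells that converge to no stable attractor —
in practice cells lying exactly on the separatrix, which converge to the
saddle — stay unresolved rather than being force-assigned; on symmetric
models the grid diagonal is exactly such a line. The separatrix estimate
collects midpoints of label-changing grid edges plus unresolved cells
flanked by the two basins, ordered along the $A + P$ direction. It is an
estimate accurate to one grid cell, not a stable-manifold computation.

## The model sampler

`sample_models()` draws loop parameters log-uniformly within
$\gamma \in [0.5, 10]$, $\delta \in [0.5, 2]$, $h \in [1, 4]$,
$\tau \in [0.5, 2]$ (stimulus fixed at 1), using R's seeded
Mersenne–Twister stream and restoring the caller's RNG state.
Log-uniform sampling represents weak and strong loops evenly on the
multiplicative scale on which these parameters act, and the ranges
straddle the bistability boundary so that default draws cover both
regimes (a 25-redraw cap guards the degenerate case). These fixtures
exercise the code across regimes; they are synthetic by construction and
do not emulate features of experimental data — measurement noise,
non-Hill dose–response shapes, parameter correlations, or slow
timescale separation between the two arms — so passing tests demonstrate
correctness of the dynamical analysis, not calibration to any biological
measurement.

## Problem sizes

The shipped tests and the reproduction script use: 2000-point bracketing
grids (5000 near the pitchfork), a $10^5$-point reference grid for the
oracle comparison on 200 sampled models, 101-point stimulus sweeps,
200-step hysteresis protocols, and $50 \times 50$ basin maps (smaller
grids in unit tests). These sizes resolve every feature of the canonical
model by a comfortable margin; all of them are plain arguments and scale
up directly.

## Known limitations

* Single-Hill arms cap multistability at two stable states; richer
  response shapes (and hence higher multistability) are outside the
  implemented class.
* Fold detection assumes the equilibrium count changes by exactly 2
  between sweep grid points; a grid so coarse that two folds fall in one
  interval is reported as an error instructing a finer grid.
* The downstream pathogenic cascade (Aβo–PrPC–mGluR5, Fyn, tau, NMDAR)
  and any fit of the loop parameters to experiments are out of scope;
  the package analyses the switch itself.
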