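---
title: "tessella: models, mechanics, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tessella: models, mechanics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tessella)
```

# The model

tessella simulates a two-dimensional plant tissue as a polygonal mesh of
well-mixed compartments.  Three layers of dynamics are compiled into one
ODE system:

1. **Chemistry.**  Reactions are written as arrows (`"2A + B -> 3A"`)
   with a rate law.  Mass action contributes
   $(f_j - e_j)\,k\prod_i X_i^{e_i}$ to species $U_j$, where $e$, $f$ are
   the reactant and product stoichiometries.  Regulatory laws (Hill,
   GRN, S-System, NHCA, rational, Michaelis–Menten, MWC) produce their
   targets at a saturating rate; catalytic arrows expand into elementary
   steps with generated bound-complex species (`X_E`), which conserves
   total enzyme exactly.  Every single-cell arrow is replicated into
   every cell automatically.

2. **Intercellular coupling.**  Fick diffusion across the wall $k$
   between cells $i, j$ gives
   $d[X_i]/dt \mathrel{+}= (\ell_k/A_i)\,\beta\,([X_j]-[X_i])$; a
   boundary permeability exchanges with a zero-concentration exterior
   (omitted = impermeable boundary).  Facilitated transport uses paired
   positive directed wall fluxes, and the intercellular GRN ("action at
   a distance") drives a species in each adjacent cell through a
   logistic response.  In the amounts basis the diffusion operator is a
   weighted graph Laplacian: symmetric, zero column sums on a closed
   tissue, non-positive eigenvalues — the package tests assert exactly
   these properties.

3. **Mechanics.**  Each wall is an overdamped Hookean spring with rest
   length $\delta_r$; each cell pushes outward with pressure $P_a$.
   Vertex velocity = $\sum_r k_r(\mathbf{x}_j-\mathbf{x}_i)
   (1-\delta_r/\ell_r) + \sum \tfrac12 P_a \ell_r \mathbf{n}$, the
   wall's pressure force being split half to each endpoint.  Rest
   lengths grow irreversibly under tension,
   $\dot\delta_r = \mu_r\,\Theta(\ell_r-\delta_r)$, and concentrations
   are diluted by $-[X]\,\dot A/A$ as cells grow.

Cell division triggers when the cell's area (or a configured species)
crosses a normally distributed threshold assigned at birth.  The wall is
placed by the modern Errera rule — the shortest chord that bisects the
area — or by minimising the weighted potential
$V = w_A V_A + w_L V_L + w_e V_e + w_g V_g$ over the central angles of
the endpoints.

## A note on the sign conventions of the mechanics

The force form actually integrated is the "implementation" form: an
*extended* spring ($\ell > \delta$) pulls its endpoints together.  This
is the only sign convention under which a single square cell shows the
documented behaviour: its perimeter obeys

$$\frac{1}{L}\frac{dL}{dt} = P - 2k + \frac{2k\Delta}{L},$$

derived by summing the vertex equations for a square (each vertex sees
two springs of force $k(1-\delta/\ell)\ell$ along the sides and pressure
$\tfrac12 P \ell$ on each incident wall).  For $P < 2k$ the perimeter
relaxes sigmoidally to $L^* = 2k\Delta/(2k-P)$ — with $k=1$, $P=1$,
$\Delta=4$, $L^* = 8$ — and for $P \ge 2k$ growth is unbounded.  This
closed form is the oracle for the mechanics integration tests.

## The perpendicularity potential

The wall-placement potential $V_\perp(\mathbf v) = \mathbf v\cdot
\mathbf W + \epsilon_\perp \Delta/d$ is reported per oriented candidate
(`potential_components()`), but a wall is orientation-free: taken
literally over both orientations of $\mathbf W$ the raw dot product
would reward *anti-parallel* walls ($-1$) over perpendicular ones
($0$).  The minimiser therefore scores each wall by its worse
orientation, $|\mathbf v \cdot \mathbf W| + \epsilon_\perp\Delta/d$,
which is minimal exactly for perpendicular walls, as the model intends.
Degenerate axes (isotropic cells or velocity fields — e.g. a regular
hexagon) are detected by an eigenvalue-gap test and the corresponding
component is dropped for that division with a warning.

## Control functions

The GRN-family laws accept `logistic` ($1/(1+e^{-x})$) or `sigma`.  The
sigma variant is implemented as

$$f(x) = \tfrac12\left(1 + x/\sqrt{1+x^2}\right),$$

a monotone increasing saturating function with $f(0)=\tfrac12$ (any such
function serves the purpose; this one is smooth and algebraic).  Note
its tails decay algebraically, much slower than the logistic — with
strongly negative arguments the response is small but not
astronomically so, which matters for the WUS model's contrast (below).

# Numerical choices

* **Integrator.**  No ODE-solver package is available in the supported
  environment, so the package carries an adaptive Dormand–Prince 5(4)
  pair with cubic-Hermite dense output (`ode_rk45()`), default
  tolerances rtol $10^{-6}$ / atol $10^{-9}$ (overridable per run).
  The three demonstration models are non-stiff enough at their
  published parameters for an explicit method within test budgets.
* **Events.**  Division thresholds are watched on every accepted step;
  an upcrossing is located by bisection on the Hermite interpolant and
  the integration stops exactly there.  Simultaneous crossings are
  processed in cell-index order.  One RNG stream, keyed by the run
  seed, serves threshold draws and tie-breaks in event order, making
  growing runs bit-reproducible; `run_growing(resume = )` continues a
  previous run (RNG state included), and a chunked run is bit-identical
  to an uninterrupted one when chunks end at division events.
* **Negative concentrations.**  The RHS evaluates on
  `pmax(C, 0)` (regulatory laws assume non-negative inputs); sampled
  states are clipped at 0 with a warning when the undershoot exceeds
  $-10^{-9}$.
* **Fixed species.**  Dirichlet species are carried in the state vector
  with their derivative forced to zero — behaviourally identical to
  excluding them, and much simpler across division-driven recompiles.
* **Voronoi templates.**  Cells are built by clipping the region
  polygon against perpendicular-bisector half-planes, visiting other
  centers nearest-first with the standard $2\times$ max-radius cutoff;
  curved region boundaries are polygonalised (96 segments).  Degenerate
  center sets are retried with a logged jitter.
* **Mesh surgery.**  Wall endpoints within $10^{-6}$ of an existing
  vertex snap to it; split edges partition their rest length
  proportionally to length (the alternative — resetting to actual
  length — would erase stored strain); the new wall is born at rest.
  After surgery the tissue is re-validated and the model recompiled, so
  location indicators (L1/L2/TIP) are re-evaluated after every
  division.
* **Errera search.**  One endpoint is scanned densely along the
  perimeter (240 positions), the equal-area partner is found by
  monotone root bracketing to $10^{-12}$, and local grid minima are
  polished with golden-section refinement; global ties (symmetric
  cells) are broken uniformly at random.

# The demonstration models and their stated world

Three ready-to-run models ship with the package.  Published parameter
values are their defaults; the handful of values the source leaves open
are fixed once here, with the reasoning.

## Brusselator (`brusselator_model`)

`0 <-> A` (a, β), `2A + B -> 3A` (c), `A -> B` (b), both species
diffusing with equal interior and boundary permeability.  With
a = β = c = 0.1 the fixed point is $A^\ast = a/\beta = 1$,
$B^\ast = b\beta/(ca) = 10b$.  Linear analysis of the well-mixed system
gives trace $= b - 0.2$: **b = 0.25** (no published value) puts the
single cell on a limit cycle, which is what sustained oscillations and,
with $D_A = 0$, frozen heterogeneous patterns require.  The initial
state is the fixed point with a ±50% uniform random per-cell
perturbation (`perturb = 0.5`): the patterned regimes here are
excitable rather than linearly unstable — the open boundary drains B
and stabilises the drained low state, so a finite kick is needed to
ignite spikes.  On the packaged 169-cell hexagonal template the
stationary maxima counts decrease with $D_B$ (24 / 8 / 4 at
$D_B$ = 0.1 / 0.5 / 1 under seed 7); the counts are template-dependent,
which is why the tests fix the template and assert the qualitative
ordering, not absolute counts.

## WUS/CLV niche (`wus_model`)

The Brusselator supplies a positioning signal A; boundary cells stand in
for the omitted L1 layer and hold the CLV-like signal Y **fixed at
y_boundary = 1** (unpublished; any positive value rescales $T_{WY}Y$),
from where Y diffuses inward and decays.  W is produced through a
sigma-controlled GRN response to (Y, A) with the published weights
($T_{WY} = -25$, $T_{WA} = 0.5$).  Because the sigma tails are
algebraic, the W contrast is carried by the ratio of $|T_{WY} Y|$
between center and rim, so the fixture tissue must span a few Y decay
lengths: the packaged fixture is a mirror-symmetric half-hex dome
(`dome_template(5, side = 3)`, 51 cells).  Wild type yields one
connected high-W domain at the dome center (threshold: half the maximum
W).  Ablation is modelled by deleting a central column of cells before
compilation *without* granting the wound edge fixed Y (dead cells do
not signal) — the Y field then sags on both sides of the wound and two
mirror-image W domains appear.  The packaged experiment and its
domain counts are template-dependent statements; the monotone decrease
of Y with graph distance from the fixed boundary is not.

## Organizer-maintained growth (`organizer_growth_model`)

The published network (U produced in TIP, V in L1, W activated by U,
repressed by V, self-activating; degradation through Z, which U
suppresses; X relaying W's feedback onto V; impermeable epidermis) with
published rates, on a larger dome fixture (`dome_template(7, side = 4)`,
92 cells).  The values the source leaves open interlock mechanically,
and fixing them taught us the model's central constraint: **the
pressure contrast between the W-expressing niche and its W-free
neighbours must stay small** (about 5x or less).  A polygonal cell
whose walls are pure springs has no bending energy; its only resistance
to being folded flat by higher-pressure neighbours is its own internal
pressure, and a W-free cell has almost none ($p_0 = 0.001$).  Every
parameterisation we tried with niche W of order 4-10 (pressure ratio
15-40) eventually inverted a flank cell and drove the geometry
singular.  The frozen choices are:

* **TIP = the top half of the bounding box** (`tip_frac = 0.5`): the
  dome fixture is itself the meristem apex, so "the cells at the tip"
  are its upper half.  This raises apical U to about 7, which switches
  the W response on *directly* ($22.5\,U > |T_{VW}| V$) with no
  reliance on the self-activation latch, so no preset initial W field
  is needed.
* **k7 = 200** (base production of Z): with $Z \approx k_7/(k_8 U)$
  this puts niche W at order 1 ($W_{\max} \approx 1.3$), keeping the
  niche/bulk pressure ratio near 5.
* **spring k = 0.002**: places $2k$ *between* $p_0$ and the niche
  pressure: every cell relaxes toward a roughly 1.8x larger
  equilibrium area (bounded growth, $P < 2k$) and divides, matching
  the published clone map in which clones appear throughout the
  tissue, while the niche ($P > 2k$) grows indefinitely and divides
  fastest.
* **division threshold**: area, mean $1.1\times$ the initial mean cell
  area, sd 8% -- low enough that the bounded bulk expansion carries
  most cells over it.

The scaled-down maintenance experiment (100 divisions on the desk; the
published scale of 500 is reachable with the same call and a larger
division budget) asserts that the high-W domain stays a single
connected component anchored at the apex, seed-reproducibly.  By
division 100 a minority of squeezed low-pressure cells are
geometrically folded (self-intersecting) even in this regime -- the
slow version of the instability above; their areas remain positive and
the chemistry well-defined.  This is the documented boundary of the
mechanical model, not of the implementation.

# What the synthetic world does and does not establish

All tissues are generated (hex arrays, clipped Voronoi, the dome) and
all initial conditions are parametric.  A green test establishes that
the *mechanisms* — mass-action compilation, Laplacian diffusion,
spring-pressure growth, threshold division, wall placement — behave as
derived, and that the three demonstration networks reproduce their
documented qualitative outcomes on the packaged fixtures.  It does not
establish quantitative correspondence with any real meristem: real L1
segmentations are irregular, real walls curve, and real division
thresholds are not normal — none of which the fixtures emulate.

# Known limitations

* Explicit integration only; models with much faster wall transfer than
  the demonstration set will want smaller tissues or looser tolerances.
* Nothing prevents a vertex model from self-intersecting under extreme
  pressure imbalance; the engine surfaces the resulting zero-area
  geometry error rather than repairing it.
* Wall compartments (reactions *in* the wall), curved walls, stochastic
  kinetics, and 3D meshes are out of scope.
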