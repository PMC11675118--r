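---
title: "Cooperative-motion Monte Carlo for a crowded dimer-solvent lattice liquid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative-motion Monte Carlo for a crowded dimer-solvent lattice liquid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dllmc)
```

## The model

`dllmc` simulates a dense two-dimensional liquid on a fully occupied
triangular lattice.  Three species share the lattice: solvent monomers
(one site each), dimers (two *mers* joined by a rigid nearest-neighbor
bond), and immobile, impenetrable obstacles.  The model is athermal: the
only interaction is excluded volume, enforced by single occupancy, so no
Boltzmann acceptance criterion exists and every geometrically admissible
move is taken.

Because every site is occupied, no molecule can move alone.  Transport
happens through the *dynamic lattice liquid* (DLL) mechanism: at each
Monte Carlo step every non-obstacle site draws an independent uniform
direction toward one of its six neighbors; the cycles of the resulting
successor map — closed displacement loops of at least three sites — are
the only pathways along which molecules can simultaneously replace one
another.  This satisfies the continuity equation by construction and
produces the correlated, hydrodynamics-like motion characteristic of
dense liquids.  One MC step is the time unit; the lattice constant is the
length unit.

Compositions follow the standard conventions: the obstacle concentration
is $c = n/L^2$ and the dimer concentration $d = 2m/L^2$ (fraction of
sites covered by mers), with the remainder solvent.

## One Monte Carlo step

Each step performs:

1. **Direction field.** Every non-obstacle site gets a uniform direction
   in $\{0,\dots,5\}$; obstacles get none and therefore can never sit on
   a loop.
2. **Loop finding.** The cycles of the successor map are enumerated.
   Cycles of length 2 (two molecules attempting a direct swap) are
   tallied and always rejected; sites on no cycle are immobile for this
   step.
3. **Constraint validation.** Starting from all candidate loops, the
   engine repeatedly sweeps the loops in ascending order of their
   smallest site index and rejects:
   * `bond_break` — any loop whose execution, given the currently
     accepted set, would leave some dimer's mers at non-nearest-neighbor
     separation;
   * `bond_cross` — any loop containing a moving molecule whose
     spacetime path passes through a moving dimer bond (below).

   Sweeps repeat until none rejects; the accepted set shrinks
   monotonically, so the fixed point exists and the deterministic order
   makes runs reproducible across platforms.
4. **Synchronous execution.** Along every accepted loop each molecule
   replaces its successor; unwrapped displacement accumulators advance by
   the Cartesian unit vector of each hop and $t$ increases by 1.

### The crossing predicate

The rule that a molecule may not "jump over" a dimer bond needs a
geometric definition, which we keep behind a single predicate
(`crossing_test()`) so alternatives can be swapped and compared.  All
positions interpolate linearly in the step fraction $s \in [0,1]$.  With
bond endpoints $b_1(s), b_2(s)$ and moving point $p(s)$, the signed area
$f(s) = (b_2 - b_1) \times (p - b_1)$ is quadratic in $s$; the move is a
crossing iff $f$ has a root $s^\* \in (0, 1]$ at which $p$ projects
*strictly inside* the segment.  Endpoint contact — the molecule entering
the site a mer vacates — is excluded, and a zero-length path never
crosses.

Two facts make this predicate complete rather than merely heuristic.
First, a *static* bond can never be crossed: hops and bonds are both
lattice edges of a planar graph and only meet at shared sites, so the
test is only invoked for moving bonds.  Second, bond-bond pass-through
needs no separate rule: two moving unit segments can only begin to
overlap through an endpoint lying on the other segment's interior (mer
paths are lattice edges and never cross each other mid-edge), and that
contact is exactly what the predicate rejects for the mer in question.
Rejection is attributed to the loop carrying the jumping molecule; the
bond's own loop is then re-examined only through the `bond_break` rule in
later sweeps.

A further geometric bound keeps the step cheap: for unit hops a crossing
is impossible unless the mover starts within graph distance 3 of a bond
endpoint, so only that neighborhood is scanned.

## Initialization

Obstacles are placed uniformly at random (or supplied explicitly, so a
trajectory ensemble can share one obstacle matrix).  Dimers are then
placed by random sequential adsorption (RSA) on edges whose endpoints are
both free.  RSA alone jams near 91% edge coverage, below what the
densest studied composition requires ($d = 0.70$ with $c = 0.28$ covers
about 97% of the non-obstacle sites), so when RSA stalls a
vacancy-diffusion stage takes over: a random vacancy either pairs with an
adjacent vacancy to place a new dimer or exchanges places with the far
mer of an adjacent dimer (a dimer flip), letting vacancies random-walk
until they meet.  This both reaches the target count and relaxes the
packing toward equilibrium.  The budgets (1000 RSA attempts per dimer,
2000 vacancy moves per site, 20 restarts) have never been reached in
practice except for genuinely infeasible compositions, which raise an
`infeasible-packing` error.  Remaining sites become solvent.

## Observables

All MSD-type quantities use unwrapped coordinates; the dimer observable
is the center of mass of its two mers (possibly an edge midpoint, treated
in continuous coordinates).

* `msd()` — $\langle \Delta r^2(t) \rangle$ averaged over molecules and
  trajectories; by default single-origin ($t=0$), matching the
  many-independent-trajectories protocol; a multi-origin mode exists for
  desk-scale variance reduction and is flagged in its statistic name.
* `non_gaussian()` — the two-dimensional non-Gaussian parameter
  $\alpha_2(t) = \langle \Delta r^4 \rangle / (2 \langle \Delta r^2
  \rangle^2) - 1$, zero for Gaussian displacements; $\alpha_2(0) := 0$
  resolves the $0/0$ limit.
* `end_to_end_acf()` — $\langle \cos\varphi \rangle(t) = \langle R(0)
  \cdot R(t) / R^2(0) \rangle$ for the unit dimer end-to-end vector, the
  rotational-relaxation monitor.
* `position_acf()` — $\rho(t)$, the fraction of molecules occupying
  their $t = 0$ *site* (wrapped identity, so a molecule that wanders and
  returns counts again; $\rho$ need not be monotone).  Implemented for
  solvent by default with a species switch, since that is how the
  quantity is used for the caging analysis.
* `trapped_fraction()` — molecules whose site never changes at any
  sample of a window, plus $\rho(t)$ recomputed over the complement.
* `loop_statistics()` — loop-length distributions, per-step mobility and
  rejection-reason rates from the engine tallies.

## Diffusion analysis

`fit_alpha()` takes the least-squares slope of $\log \mathrm{MSD}$
versus $\log t$ (samples are log-spaced, so unweighted least squares is
near-uniform in $\log t$); the walk dimension is $d_w = 2/\alpha$.
`fit_diffusion_coefficient()` divides the linear MSD slope by 4 (the
two-dimensional Einstein relation) and reports $D$ as valid only when
$\alpha$ on the same window passes the gate.  The default gate is the
symmetric $0.9 < \alpha \le 1.1$, because finite sampling scatters
$\alpha$ slightly above 1 for genuinely Fickian data; the one-sided gate
$0.9 < \alpha < 1$ is available as a strict mode.  Default windows are
$t \in [1, 10^2]$ for the short-time coefficient and the last decade of
the run for the long-time coefficient — at desk scale the latter replaces
the production-scale convention ($t > 10^7$), which presumes runs of
$10^9$ steps.  `fit_exponential_decay()` checks $D_{SH}(c) = D_0
e^{-ac}$ on the log scale, and `diffusion_ratio()` propagates
first-order standard errors into solvent/dimer ratios.

## Percolation

`spanning_probability()` estimates, per open-site probability $p$, the
chance that open sites form a cluster wrapping the periodic box,
detected by union-find with displacement tracking: when a union joins
two sites already in one cluster but with inconsistent relative
displacement, the cluster winds the torus.  The wrapping criterion has
sharper finite-size behavior than side-to-side spanning and no boundary
ambiguity on a periodic box.  `estimate_threshold()` interpolates the
$p$ at which the wrapping probability crosses one half, averages the
per-size estimates and bootstraps the uncertainty.  At criticality the
any-direction wrapping probability is a universal constant near 0.69, so
the half-crossing sits slightly below the threshold at finite $L$; at
$L \in \{64, 128\}$ the residual bias is several parts in a thousand,
well inside the accuracy we claim.

## Design choices and numerical details

* **Geometry.** Axial coordinates on a rhombic $L \times L$ periodic
  box; neighbor offsets $(1,0), (0,1), (-1,1), (-1,0), (0,-1), (1,-1)$,
  so direction $k$ and $(k+3) \bmod 6$ are inverses.  All geometric
  tests use the Cartesian embedding with minimal-image displacements.
  $L \ge 3$ is required (no loop fits otherwise).
* **Rounding.** $n = \mathrm{round}(cL^2)$, $m = \mathrm{round}(dL^2/2)$
  (ties to even); realized concentrations are reported beside the
  requested ones in every composition object and manifest.
* **Initialization order.** Obstacles, then dimers, then solvent.  The
  obstacle ensemble is thereby independent of $d$.
* **Loop winding.** The hop vectors of a loop sum to zero exactly for
  contractible loops; a loop that winds the torus sums to a lattice
  translation (a multiple of $L$) instead, so the center of mass is
  invariant modulo the translation group rather than absolutely.  This
  is a property of periodic boxes, not an artifact.
* **Tolerances.** Bond lengths are compared against 1 with tolerance
  $10^{-6}$ (the nearest competing separations are $\sqrt 3$ and 2);
  crossing roots use $10^{-9}$; the strict-interior margin for the
  segment projection is $10^{-9}$.
* **Determinism.** All randomness, including inside the compiled core,
  flows through R's RNG, so one `set.seed()` reproduces a run exactly;
  ensembles derive per-matrix and per-trajectory sub-seeds from the
  master seed and record them in the run manifest.
* **Containers.** Snapshots and trajectory stores are self-describing
  JSON/CSV text containers that round-trip losslessly (17 significant
  digits); observables are tidy CSV.

## What the test problems do and do not show

The study conditions behind the quantitative checks are scaled down from
production scale ($L = 256$, $10^9$ steps, tens of thousands of
trajectories) to desk scale: $L = 64$, $10^5$ steps and 8 trajectories
for the obstacle-free Fickian check, $3 \times 10^5$ steps over several
obstacle matrices for the crowded composition $c = 0.28$, $d = 0.70$,
and 500 realizations per grid point for percolation.  These sizes were
chosen so the whole battery runs on one workstation core in minutes
while each estimate's sampling error stays well inside its acceptance
band.

Two caveats follow from the scale-down.  First, long-time windows here
end at $10^5$–$3 \times 10^5$ steps; slow processes that only separate
beyond that (the deep subdiffusive regime of dimers near the percolation
threshold) are visible only as trends.  Second, the late-time level of
the solvent position autocorrelation at the most crowded composition is
sensitive to the measurement window in a way the never-moved fraction is
not: our runs reproduce the never-moved fraction (about 9% at
$c = 0.28$) quantitatively, but $\rho(t)$ has already decayed well below
its production-scale plateau level by $3 \times 10^5$ steps, and the
additional caged-but-rattling population that sustains that plateau at
production scale does not survive the shorter, unaged window.  The acceptance battery reports both numbers as
computed; only the trapped fraction is treated as scale-robust.

The synthetic generator emulates random obstacle matrices with
RSA-plus-repair dimer packings.  It does not emulate aged or annealed
configurations (no pre-equilibration is applied before measurement),
polydispersity, chains longer than dimers, vacancies, or any energetic
interaction — all outside the model.

## Known limitations

* Single-threaded; production-scale parameter sets ($L = 256$, $10^9$
  steps) are accepted by the configuration layer and flagged
  `cluster_scale`, but are cluster work, not desk work.
* The crossing rule is one documented interpretation of a pictorial
  constraint; it is isolated behind `crossing_test()` precisely so a
  different convention can be compared.
* $\rho(t)$ and the trapped fraction evaluate at sampled times only; an
  excursion between two samples is invisible.  The default schedule (20
  points per decade) makes this a negligible correction.
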