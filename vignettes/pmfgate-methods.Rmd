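---
title: "Methods: free-energy maps and pH-gating models in pmfgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy maps and pH-gating models in pmfgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfgate)
```

## What the package computes

Potassium channels conduct K⁺ through a narrow selectivity filter whose
binding sites (S0–S4, plus the water-filled cavity below) hold two to
three ions at a time. Two kinds of quantitative analysis recur in
studies of channels such as KcsA:

1. **Free-energy maps of ion permeation.** The potential of mean force
   (PMF) over reaction coordinates describing the pore-axis positions of
   the filter ions — here `z12` (center of mass of the two outermost
   ions) and `z3` (the innermost ion), both relative to the filter's
   center of mass — is estimated by umbrella sampling: many harmonically
   biased simulations are combined by the weighted histogram analysis
   method (WHAM), with windows placed adaptively along the valleys of
   low free energy. Wells of the map are ion-occupancy states; saddle
   heights between them are the barriers that control conduction
   (roughly, barriers above ~6 kcal/mol block permeation, barriers of
   2–3 kcal/mol permit it).
2. **pH-gating dose-response models.** Single-channel open probability
   versus pH is summarized empirically by the Hill equation and
   mechanistically by a two-sensor Monod–Wyman–Changeux (MWC) model of
   a homotetramer with proton sensors whose acid dissociation constants
   differ between the closed and open conformations.

`pmfgate` implements both pipelines at desk scale. Because all-atom
molecular dynamics is far outside a laptop budget, the sampling engine
is a Brownian-dynamics integrator on analytic free-energy landscapes:
every statistical property of the umbrella/WHAM machinery can then be
validated against the exactly known surface.

## The Brownian stand-in for molecular dynamics

`simulate_rc()` propagates the overdamped Euler–Maruyama update

$$z \leftarrow z - \frac{D}{k_BT}\,\nabla\!\left(U + w\right)\,\Delta t
  + \sqrt{2D\Delta t}\;\xi,\qquad \xi \sim \mathcal N(0,1),$$

with reflecting boundaries at the domain edges. There is no inertia:
only the stationary Boltzmann distribution $\propto e^{-(U+w)/k_BT}$
matters for free-energy recovery, and the overdamped chain converges to
it (the test suite verifies this via Kolmogorov–Smirnov distance against
quadrature). Reflection leaves interior Boltzmann weights essentially
untouched as long as the walls sit several $k_BT$ above the wells,
which all shipped landscapes guarantee.

Parameters and defaults (all tunable via `brownian_params()`):

| parameter | default | units | rationale |
|---|---|---|---|
| temperature | 323.25 | K | the temperature of the channel simulations being emulated; $k_BT \approx 0.642$ kcal/mol |
| diffusion coefficient $D$ | 0.5 | Å²/ps | order of magnitude of K⁺ in water |
| timestep $\Delta t$ | 0.002 | ps | keeps the drift per step ≪ the softest relaxation length; a pre-flight domain scan raises an error if $|(\!D/k_BT)\nabla(U{+}w)\,\Delta t|$ exceeds 0.5 Å anywhere |
| sampling interval | 0.01 | ps | a 600 ps window minus 100 ps equilibration then yields exactly 50 000 retained samples |

$k_B = 0.0019872041$ kcal/mol/K is fixed package-wide so unit
conversions are bit-exact across modules. Trajectories are
bit-reproducible for a fixed seed (the integrator draws from R's RNG
stream).

Samples are correlated on the scale of the biased relaxation time
$k_BT/(D\,k_{tot}) \approx 0.06$ ps; WHAM point estimates are unbiased
under correlation, but effective sample sizes are roughly 4–5× smaller
than raw counts, which the error analyses below absorb empirically.

## Analytic landscapes

Four differentiable families are available (`analytic_landscape()`):
flat, harmonic, a 1D quartic double well with exact barrier height, and
the 2D `permeation_map` — a chain of wells joined by a smooth valley
that mimics the topology of filter-occupancy maps
(S1–S3–Cav → S0–S2–S4 → release). The longitudinal profile
interpolates well depths with cubic smoothsteps plus a symmetric C¹
bump per segment; the bump amplitude is solved numerically so that the
minimax barrier between adjacent wells equals the requested height to
better than 10⁻⁶ kcal/mol. Because any path between adjacent wells must
cross the vertical line through the saddle, where the transverse term
only adds energy, the designed 1D barrier *is* the 2D minimax barrier —
this is what makes the family usable as an exact oracle.
`toy_permeation_map()` ships an "open" preset (2.5 kcal/mol barriers)
and a "closed" preset (8 kcal/mol barriers, i.e. > 6).

## WHAM

`wham_solve()` iterates the standard self-consistent equations

$$P(b) \propto \frac{\sum_i n_i(b)}{\sum_i N_i\,e^{(f_i - w_i(b))/k_BT}},
\qquad
f_i = -k_BT\,\ln \sum_b P(b)\,e^{-w_i(b)/k_BT}$$

on a half-open analysis grid (0.1 Å default spacing), with the bias
evaluated at bin centers (at this spacing the within-bin variation of a
20 kcal/mol/Ų bias contributes $\mathcal O(10^{-2})$ kcal/mol, which
the test suite bounds against a sample-based MBAR cross-check).
Numerical choices:

* **Convergence** is declared at $\max_i |\Delta f_i| < 10^{-7}$
  kcal/mol (far below thermal noise), capped at $10^5$ iterations;
  hitting the cap flags the result instead of raising.
* **Exponential guarding.** The iteration is computed in a factored
  form $e^{f_i/k_BT}\,e^{-w_i(b)/k_BT}$ with the first offset
  re-anchored to zero every sweep, so distant window/bin pairs
  underflow harmlessly to zero weight and nothing can overflow; the
  two inner sums are BLAS matrix–vector products.
* **Undefined bins.** Bins with zero total counts are excluded from
  normalization and reported as `NA` — an explicit "undefined" marker
  that every downstream statistic respects. The minimum over sampled
  bins is exactly 0 by construction.
* **Connectivity.** Windows that share no sampled bin cannot be tied
  together by WHAM; `wham_solve()` detects the components of the
  window-overlap graph and aborts with the component list rather than
  returning an arbitrarily gauged map.

## Self-learning adaptive window placement

`run_adaptive()` grows the window set from a single seed on a 0.5 Å
lattice: simulate the newly proposed windows (600 ps each, 100 ps
equilibration, force constant 20 kcal/mol/Ų), re-solve WHAM over all
windows (warm-started from the previous round's offsets — gauge
invariant and much faster), then propose every not-yet-simulated
lattice neighbor (8-connected by default) whose estimated free energy
is below the 12 kcal/mol creation limit. The loop stops when a round
proposes nothing.

The frontier estimate is bilinear interpolation of the current PMF at
the candidate center. Where any of the surrounding bins is undefined,
the estimate falls back to the minimum defined free energy among the
bins whose centers lie within 1.5 grid spacings of the candidate; a
candidate with no defined bin nearby is not proposed — sampling has not
reached it, which for the shipped landscapes coincides with terrain
many $k_BT$ uphill. The fallback is deliberately optimistic
("follow the valleys"), bounded by the re-estimate once the window has
actually been sampled. A new window starts from the retained sample of
its completed neighbors closest to the new center (ties: lowest window
index, then earliest sample); the master seed deterministically derives
every per-window seed, so whole run transcripts are reproducible.

**What exactness requires.** On maps whose sub-limit terrain stays
below ~11 kcal/mol with per-step climbs ≲ 4 kcal/mol, and whose
excluded nodes sit ≥ 16 kcal/mol behind ramps that keep the
12 kcal/mol contour at least ~0.25 Å away from them, the final window
set equals a flood fill of the analytic surface thresholded at the
limit — node for node, across seeds. The acceptance suite runs three
such engineered maps (an open two-well pair, the same geometry closed
by a 22 kcal/mol barrier, and a straight three-well chain). On maps
with *curved* valleys the min-over-neighbors fallback can legitimately
see sub-limit bins of the bending valley within 0.15 Å of a node whose
own free energy is above the limit, and occasionally adds that rim
node; the diagonal-valley test therefore asserts completeness plus
confinement to the oracle set and its immediate lattice rim, not exact
equality. This mirrors how the method behaves on real systems: the
frontier rule is a heuristic whose small over-coverage costs only
simulation time, never correctness of the final map.

## PMF post-processing

* **Combining runs** (`combine_runs()`) pools the windows of
  independent runs — typically initiated in different ion-occupancy
  states — into a single joint WHAM solve, in the same spirit as
  combining forward and backward perturbation legs; it is *not* an
  average of per-run maps. Pooling the halves of one run reproduces the
  original solution bit for bit. No error bars are attached to combined
  maps (their statistical error is not readily definable); per-run
  error maps are reported instead.
* **Interval error** (`interval_error()`) re-solves WHAM on disjoint
  consecutive 100 ps slices of the post-equilibration sampling of every
  window (a 600 ps window thus yields exactly five), offsets each
  interval map by a least-squares fit to the final map over the grid
  points with final free energy < 6 kcal/mol (closed form: the mean of
  final − interval over the mask, verified against a brute-force scan),
  and reports the per-bin standard deviation over the last five offset
  interval maps. The statistic is translation invariant and scales
  roughly as $1/\sqrt{\text{samples per slice}}$.
* **States and barriers.** `find_states()` returns strict local minima
  (8-neighborhood) below a cutoff, merging near-duplicates to the lower
  one. `minimax_path()` computes the widest path between two states —
  the path minimizing the maximum free energy, found by a modified
  Dijkstra over defined bins — because saddle heights, not integrated
  actions, are what one reads off an occupancy map. It is validated
  against exhaustive threshold-connectivity enumeration on small grids.
* **Occupancy and permeation counting.** `classify_occupancy()` maps
  pore-axis coordinates to sites between strictly decreasing boundary
  cutoffs and counts permeation events with hysteresis: an ion must
  fully cross from below the cavity's lower cutoff to above the
  extracellular cutoff, in order, so boundary chatter never counts.
  Site boundaries are explicit inputs; the shipped defaults belong to
  the synthetic knock-on cycle of `toy_permeation_cycle()` only and
  pretend no atomic geometry.

## The gating models

The Hill summary of a dose-response is

$$P_o(\mathrm{pH}) = \frac{P_{o,max}}{1 + 10^{(\mathrm{pH} -
  \mathrm{pH}_{1/2})\,n_H}},$$

and the mechanistic model is a two-sensor MWC homotetramer,

$$P_o = \frac{L_o A_o B_o}{L_o A_o B_o + A_c B_c},\qquad
  A_x = \left(1 + 10^{pK_{a1,x} - \mathrm{pH}}\right)^4,\;
  B_x = \left(1 + 10^{pK_{a2,x} - \mathrm{pH}}\right)^4,$$

with the subunit exponent fixed at 4 (a tetramer, not a fit parameter)
and absent sensors encoded as a factor of exactly 1 (numerically exact,
matching the "–" entries of the published table). Evaluation is in the
log domain, so $L_o$ down to $10^{-15}$ and beyond neither overflows
nor loses the tail; the suite checks agreement with direct power-form
evaluation to $10^{-12}$ relative error. Note the low-pH limit
saturates at $1/(1 + 10^{-4\sum(pK_{a,open}-pK_{a,closed})}/L_o)$
rather than exactly 1 — 0.99996 for the control channel but 0.978 for
a one-sensor mutant.

**Fitting** (`fit_hill()`, `fit_mwc()`) is bounded Levenberg–Marquardt
least squares on the per-pH $P_o$ means. Unweighted is the default (the
reported sems are stored, and sem-weighting is available as an option,
but the original fits are not described as weighted). $L_o$ is fitted
on a log₁₀ scale with its standard error mapped back by the delta
method. The physical ordering $pK_{a,closed} \le pK_{a,open}$ is a box
bound on each free $pK_{a,closed}$ whenever the matching open value is
fixed; parameters that end on an active constraint are reported without
a standard error, exactly as the published table does.
`fit_mwc_two_stage()` reproduces the constrained workflow for mutants
whose sensor loses state-dependence: stage 1 frees $L_o$ and
$pK_{a1,closed}$, and when the latter climbs to its bound, stage 2 pins
it to $pK_{a1,open}$ and refits $L_o$ as the single free parameter.

A caution on identifiability: freeing $L_o$ *and* both pKa values of
the remaining sensor on a single noisy dose-response makes the model
weakly identified — $L_o$ trades off against the pKa gap, Wald
intervals stop covering (we measure ~89% at a nominal 3-SE level), and
the corresponding published $L_o$ indeed carries a ~60% uncertainty.
The coverage validation therefore uses the single-free-parameter
protocol of the original analysis; with $L_o$ alone free, 3-SE coverage
is ≥ 99% in 200-dataset Monte-Carlo per construct.

**Hill summaries of MWC curves** (`hill_summary_of_mwc()`) evaluate the
MWC model on pH 4.0–6.5 in steps of 0.05 (the experimental range plus
the upper shoulder) and fit the Hill equation with $P_{o,max}$ free,
trying a small deterministic set of starting slopes and keeping the
lowest-SSR fit. The MWC shape is not exactly a Hill curve, so the
summary depends (weakly) on the grid; the control channel's summary
comes out at $n_H \approx 5.3$, somewhat above the value fitted to the
experimental points, while the mutants' summaries land on the published
numbers.

## Synthetic dose-response data

`generate_po_dataset()` emulates a bilayer experiment: per pH,
`replicates` (default 5) independent measurements are drawn as the MWC
curve value plus normal noise (sd 0.05) clipped to [0, 1], then
tabulated as mean ± sem. What this does *not* emulate: clipping biases
the mean when the true $P_o$ sits within ~2 sd of 0 or 1 (real bilayer
scatter is also bounded but not by symmetric truncation); there is no
bilayer-to-bilayer correlation, no rundown, and no voltage dependence.
Passing the recovery tests therefore demonstrates correctness of the
fitting machinery under idealized noise, not robustness to every
artifact of recordings.

## Problem sizes used by the test suite

The suite runs entirely from generated data: 1D WHAM validations use
9–21 windows of 600 ps (50 000 retained samples each); adaptive runs
use the full 600 ps windows on 0.5 Å lattices of ≤ 117 nodes (9–27
windows per run); interval-error scaling uses 1050 ps windows; gating
Monte-Carlo studies use 200 synthetic datasets per construct. These
sizes were chosen so every stochastic assertion holds with wide margins
across seeds while the whole suite stays in the minutes range on one
core.

## Known limitations

* The sampler is overdamped and the landscapes are low-dimensional
  analytic surfaces: kinetics, inertial effects, and orthogonal slow
  degrees of freedom are out of scope by design.
* WHAM here supports 1D/2D grids and histogram (not kernel) estimates;
  no autocorrelation-based decorrelation is applied, and the package
  deliberately contains no MBAR estimator (a sample-based MBAR is
  implemented independently inside the test suite as a cross-check).
* Adaptive exploration can add rim windows beside strongly curved
  valleys, as discussed above.
* State labels are user-supplied text; the package does not infer ion
  occupancy chemistry from coordinates beyond the site-boundary
  classification.
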