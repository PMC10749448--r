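---
title: "Lone-pair decomposition of halide hydration shells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lone-pair decomposition of halide hydration shells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpshells)
```

## The problem

Halide anions in water have notoriously diffuse first hydration shells:
first-shell distances and coordination numbers reported in the literature
scatter widely, and purely radial (distance-cutoff) models cannot say which
of the 7–9 waters inside the first minimum of the ion–oxygen g(r) actually
interact with the ion. The resolution this package implements starts from the
anion's four lone pairs, represented geometrically by sites near the ion
(in ab initio simulations these are maximally localized Wannier-function
centers, carried in the trajectory as pseudo-atoms). Waters that donate a
hydrogen bond *to a specific lone pair* form a tetrahedral "tight" first
shell; the remaining first-shell waters are a "loose" shell, only mildly
perturbed by the ion's charge. The package never computes electronic
structure: lone-pair sites are input data, produced upstream or by the
bundled synthetic generator.

## The eta descriptor

For an ion–water pair, each of the 4 × 2 (lone pair, hydrogen) combinations
is scored by

\[
\eta \;=\; r^{\mathrm{LP\text{-}H}} \,\sec(\alpha/2)\,\sec(\beta/2),
\]

where \(r^{\mathrm{LP-H}}\) is the lone-pair–hydrogen distance, \(\alpha\)
the angle at the ion between the ion→lone-pair and ion→hydrogen directions,
and \(\beta\) the angle at the hydrogen between the O→H bond direction and
the hydrogen→lone-pair direction. At the ideal linear hydrogen bond
(\(\alpha=\beta=0\)) both angular weights are 1 and \(\eta\) reduces to the
lone-pair–hydrogen distance; \(\eta\) is strictly increasing in the distance
at fixed angles and in either angle away from linearity, so lower \(\eta\)
means stronger interaction. The half-angle secant form is this package's
concrete choice of angular weight: it satisfies every property the
descriptor needs (length units, smooth minimum at linearity, monotone
growth, divergence as a geometry becomes unphysical at 180°) while keeping
the linear-limit value exactly equal to the distance, which makes cutoffs
directly interpretable in Å. Angles at or beyond 180° are a domain error in
the scalar API rather than being clamped; the vectorized internal path
treats exactly-antilinear geometries as \(\eta = \infty\), which can never
become the per-pair minimum.

The per-pair descriptor \(\eta_{ij}\) is the **minimum over the eight
combinations** (ties broken to the lexicographically smallest lone-pair,
hydrogen index pair). The minimum is the only aggregation consistent with
reading \(\eta\) as an interaction-strength proxy: the pair interacts
through its strongest lone-pair contact. The same convention is used for the
\(P(\eta)\) histograms.

One periodic-boundary caveat: every interparticle vector passes through the
minimum-image convention, so for contacts farther than half the box edge the
nearest periodic image of the hydrogen relative to the lone pair may differ
from the image nearest the ion. \(\eta\) values of such distant pairs
depend on the lattice orientation and are physically meaningless — they are
far in the weak tail of \(P(\eta)\) and never affect shell assignment. The
rotation-invariance property is therefore only tested for configurations
within half the box edge.

## Shell decomposition

Two cutoffs define the decomposition. The conventional first-shell radius
`r_cut` is the first minimum of the ion–oxygen g(r) (4.00 Å for chloride,
4.37 Å for iodide; or recomputed from the data with `first_minimum()`).
The `eta_cut` separating tight from loose is placed where the \(\eta\)
distributions of the four nearest waters and of the 5th–7th nearest waters
intersect (`eta_cutoff_from_intersection()`), i.e. where membership of the
inner tetrahedron stops being the better explanation of an observed
\(\eta\). Classification is then:

* **tight**: \(\eta_{ij} <\) `eta_cut` — note no distance condition: a
  farther molecule with a strong lone-pair contact belongs to the tight
  shell;
* **loose**: not tight and \(r_{XO} <\) `r_cut`;
* **bulk**: not tight and \(r_{XO} \ge\) `r_cut`.

Both comparisons are strict, so boundary values fall outward — a
deterministic, measure-zero convention. Waters inside `r_cut` whose two
hydrogens both point into the hemisphere away from the ion (angle at oxygen
above 90°) are flagged *misoriented*: they sit in the first shell by
distance only, hydrogen-bonded to other first-shell waters rather than to
the ion. They keep their loose label — the flag annotates, it does not
create a region.

## Exchange events and residence times

Per water, the region time series is first cleaned by the transient filter:
a raw region change at time \(t\) commits only if the molecule does not
re-enter its former region within \((t, t + 0.1\,\mathrm{ps}]\); discarded
excursions are erased and scanning resumes at the re-entry. The committed
path is then parsed into exchange episodes anchored at the two endpoint
regions (tight, bulk), with the loose shell as the corridor between them:
a tight→loose departure that returns is one T–L event; one that reaches
bulk is one T–L–B event; direct tight↔bulk transitions are T–B; the
bulk-side mirrors (B–L, B–L–T, B–T) accumulate into the same undirected
columns. An episode cut off by the end of the trajectory still counts for
its shell (with the two-region category reached so far): dropping it would
bias event counts low by about half an episode per molecule, which is
material on a 10 ps trajectory. A round trip is deliberately **one** event,
not two: with that convention the direct-method residence time
\(\mathrm{MRT} = t_{\mathrm{sim}}\,\bar n / N_{\mathrm{ex}}\) converges to
the true mean dwell time \(1/k\) on Markovian test data, and
\(\mathrm{NMRT} = \mathrm{MRT}/\bar n = t_{\mathrm{sim}}/N_{\mathrm{ex}}\)
with \(N_{\mathrm{ex}}^{\mathrm{tight}} = \mathrm{T\!-\!L} +
\mathrm{T\!-\!B} + \mathrm{T\!-\!L\!-\!B}\) and
\(N_{\mathrm{ex}}^{\mathrm{loose}} = \mathrm{T\!-\!L} + \mathrm{L\!-\!B} +
\mathrm{T\!-\!L\!-\!B}\) reproduces reference residence times from
reference event counts exactly.

Two caveats established during development and encoded in the tests. First,
the kinetic-recovery tests run the filter at its smallest admissible
threshold (one frame) rather than 0.1 ps: the 0.1 ps filter *deliberately*
discards fast recrossings, which inflates the apparent residence time by
roughly the recrossing probability \(1-e^{-k_{\mathrm{return}}\cdot 0.1}\);
that is its purpose, not an estimator defect, and the 0.1 ps behaviour is
tested separately on blip sequences. Second, "a larger threshold never
commits more events" is provable only for well-resolved kinetics; on
adversarial label sequences that flip every frame, erasure can make the two
scans diverge and the larger threshold can commit more downstream changes.
The monotonicity test therefore runs on Markov-generated series sampled
well below the dwell times.

## The synthetic generator

`generate_trajectory()` produces the statistical structure the analysis
assumes, with ground-truth labels for recovery tests — not physical water.
What it emulates: four lone pairs at 0.5 Å from the ion along tetrahedral
directions (rigidly rotated by a slow random walk, 2°/frame s.d., so the
lone-pair local frame is exercised); tight waters with one O–H aimed at
their assigned lone pair (10° angular jitter, ion–H distance
N(2.25 Å, 0.1 Å) for the chloride preset, N(2.60, 0.1) for iodide); loose
waters uniform in a shell from the conventional first-shell distance to
`r_cut` with uniformly random rigid orientation; bulk waters uniform out to
the inscribed sphere; rigid ideal water geometry (O–H 0.97 Å, H–O–H
104.5°). What it does not emulate: water–water forces and hydrogen-bond
networks, polarization, vibrations, or continuous diffusion — geometry is
resampled independently each frame within the current region, so only the
region process carries dynamics. Passing tests therefore validate the
estimators and the geometric machinery, not any claim about real water.

Design choices that merit their rationale:

* **Region dynamics.** Each water follows a continuous-time Markov chain
  (tight↔loose↔bulk) discretized at `dt`, with one constraint: a
  loose→tight move requires a free lone-pair anchor, so the tight shell
  never exceeds four waters. Unconstrained per-water chains would equilibrate
  half of the tight/loose pool into "tight" regardless of the four-site
  physics; the capacity rule is what makes "tetrahedrally anchored" mean
  something. With four or fewer waters in the tight/loose pool the
  constraint never binds, so the two-state kinetic tests see a pure Markov
  chain.
* **Rate defaults** \(k_{TL} = k_{LT} = 1\,\mathrm{ps^{-1}}\),
  \(k_{LB} = 2\), \(k_{BL} = 0.6\): the loose↔bulk pair satisfies
  \(k_{BL}/(k_{LB}+k_{BL}) = n_{\mathrm{loose}}/(n_{\mathrm{loose}} +
  n_{\mathrm{bulk}})\) for the default 6/20 composition, so the declared
  shell sizes are stationary and the generator's composition parameters mean
  what they say.
* **Loose shell starts at the conventional first-shell distance**
  (3.2 Å Cl, 3.55 Å I), not below it: loose mass under the tight oxygen
  radius would push genuinely tight waters into distance-ranks 5–7 and
  contradict the structure being emulated (the loose-shell g(r) sits at
  larger distances than the tight peak).
* **Oxygen–oxygen exclusion 2.4 Å** (`min_oo`): the physical closest
  approach of water oxygens. It also guarantees every hydrogen is nearer
  its own oxygen than any other (2.4 − 0.97 > 0.97), which the XYZ reader's
  nearest-oxygen molecule assembly requires. Placement uses rejection
  sampling (100 attempts) with a deterministic radius × direction sweep as
  a fallback before a shell is declared overfull; overlap checks use
  minimum-image distances, since waters near the half-box radius have
  close periodic neighbours.
* **Determinism.** A single seeded RNG stream drives region dynamics, then
  geometry, in fixed order; identical parameters give bit-identical
  trajectories on disk.

## Numerical choices

* Histograms: 0.02 Å default bins for g(r) and P(η) (resolving the sharp
  tight-shell peaks at 14 Å box scale); r_max defaults to half the box
  edge; bins are edge-aligned half-open intervals.
* RDF normalization: exact shell volumes \(\tfrac{4}{3}\pi(r_2^3-r_1^3)\)
  and the whole-box mean partner density, also for masked subsets — so a
  masked curve and its complement sum bin-wise to the total, exactly.
  Coordination numbers are available both by direct counting and by
  integrating g(r); they agree to within one bin's discretization.
* Extremum and intersection finding: a 5-bin moving average (partial at the
  edges) smooths the curve first; the first minimum and the
  rank-distribution crossing interpolate linearly between bracketing bins;
  ties resolve to the smallest abscissa, with smoothing plateaus resolved
  by the raw curve. Raw-bin positions are reported alongside smoothed ones.
* The SDF local frame is the TRAVIS-style three-point construction: axis 1
  along ion→LP1, axis 2 orthogonalized in the LP1–LP2 plane, axis 3
  completing a right-handed set; lone-pair identity is tracked across
  frames by maximal-alignment assignment over all 24 permutations. Grids
  are normalized to mean density 1 over occupied voxels; cube files use the
  Ångström (negative voxel count) convention with the ion as the single
  atom record.

## Problem sizes in the test suite

The suite generates everything it needs at run time. Typical sizes, chosen
to give the statistical power each assertion needs: 2000-frame (10 ps)
trajectories with 30 waters for the end-to-end tetrahedral-recovery checks;
20 seeds × 2000 frames of 4-water two-state kinetics per escape rate for
residence-time recovery (three rates); 2000-point regressions; 400–1200
frame trajectories for distributional properties; and 100-frame, 10-water
instances for brute-force oracle equivalence. The full suite runs in a few
minutes on one CPU.

## Known limitations

* The generator's waters are uncorrelated between frames; time-correlation
  estimators beyond region kinetics (e.g. survival functions, hydrogen-bond
  lifetime correlations) are out of scope and untestable against it.
* Cubic boxes and a single monatomic solute only; no triclinic cells, no
  solvents other than rigid water.
* η for pairs beyond half the box edge depends on the lattice orientation
  (see above); interpret \(P(\eta)\) tails accordingly.
* The eta-cutoff intersection requires both rank distributions to be
  populated (at least seven waters) and genuinely overlapping; degenerate
  inputs raise errors rather than guessing.
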