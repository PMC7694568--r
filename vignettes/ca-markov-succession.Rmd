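---
title: "CA-Markov succession modelling of coastal wetland vegetation belts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CA-Markov succession modelling of coastal wetland vegetation belts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camarsh)
```

## The system and the question

Silty coastal wetlands such as the Yancheng coastal natural reserve organise
themselves into shore-parallel vegetation belts: *Phragmites australis* reed
marsh nearest the seawall, *Suaeda salsa* seepweed marsh seaward of it, then
bare mudflat, all migrating seaward as sediment accretes. The invasion of
smooth cordgrass (*Spartina alterniflora*), which colonises the mudflat
seaward of the seepweed belt, is suspected of squeezing the native belts
from the sea side. Because there is no uninvaded replicate of the coastline,
the natural-succession baseline must be simulated: project how the native
belts would have moved had the invader never arrived, and compare that
counterfactual with the observed maps.

`camarsh` implements that workflow end to end on dated categorical rasters:

1. **Markov estimation** (`estimate_transitions`) — a row-stochastic
   transition matrix $P_{ij}$ from a pair of dated maps, counted over cells
   that belong to a dynamic class at both dates.
2. **Annualization** (`annualize`) — conversion of a $k$-year matrix to a
   1-year step by the $k$-th matrix root.
3. **CA-Markov simulation** (`ca_step`, `ca_run`) — Markov area demands
   allocated spatially by a neighbourhood contiguity filter.
4. **Validation** (`cross_tabulate`) — confusion matrix, overall accuracy
   and Cohen's kappa between two maps.
5. **Zonation geometry** (`boundary_profile`, `movement`, `area_series`) —
   baseline-referenced mean boundary distances $L = S/D$, 1-D centroids,
   band widths and seaward movement rates.
6. **Synthetic landscapes** (`make_banded_grid`, `evolve`) — a generator of
   banded wetlands with known dynamics, so every stage is testable without
   any satellite imagery.

## Grids, baseline and distances

A `landscape_grid` is an integer lattice with a cell size (default 30 m,
i.e. 0.09 ha per cell), a calendar year, a class scheme and a
`baseline_edge` naming which raster edge represents the seawall. All
distances are perpendicular to that edge and increase seaward; a cell $i$
rows from the baseline (0-based) sits at $(i + 0.5)\,\times$ cell size, a
centre-of-cell convention chosen so that the closed forms in the tests are
exact. Nodata cells are excluded from every area and metric, and grids that
enter a pairwise operation must share shape and cell size — the study area
is a single fixed frame, so no resampling is offered.

Supported file formats are the ESRI ASCII grid (the `cellsize` header is
honoured) and plain single-band 8-bit TIFF, which carries no georeference,
so the cell size is supplied by the caller.

## The transition matrix and its annualization

$P_{ij}$ is the probability that a cell of dynamic class $i$ is class $j$
one step later. Estimation is a straight cross-tabulation normalised by
row; a class with no source cells receives an identity row so the matrix is
always exactly row-stochastic. Published matrices carry printing round-off
(a row summing to 0.9999): rows off by at most 0.01 are renormalized with a
warning, anything worse is an error.

A matrix estimated over a $k$-year interval is converted to an annual step
by the principal $k$-th root via eigendecomposition,
$P^{1/k} = V \Lambda^{1/k} V^{-1}$. Stochastic matrices need not have
stochastic roots, so negative entries are clipped to zero and rows
renormalized; the Frobenius reconstruction residual
$\lVert A^k - P \rVert_F$ is always attached to the result rather than
hidden, and is zero whenever the root is exactly embeddable (as in the
diagonally dominant matrices typical of land-cover persistence). Roots with
imaginary parts above `imag_tol` (default $10^{-6}$) are refused.
Continuous-time embedding (matrix logarithms) is deliberately out of scope.

```{r annualize-example}
M <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
root <- annualize(transition_matrix(M %*% M, step_years = 2), 1)
attr(root, "residual")  # exact recovery of M
```

## The CA-Markov step

Each annual step has a quantity side and an allocation side.

**Quantity.** Class demands in whole cells come from the Markov projection
of the current class counts, rounded by largest-remainder apportionment so
the dynamic cell total is conserved exactly. Whole-cell *transition* quotas
$T_{ij}$ are then derived by a transportation rounding of
$n_i P_{ij}$ that keeps both the row sums (source counts) and the column
sums (the rounded demands) exact.

**Allocation.** Suitability of class $c$ at a cell is the fraction of $c$
among dynamic cells in the centred `filter_size` × `filter_size` window
(default 5 × 5, truncated at edges, no wraparound — the frame is bounded by
rivers and the seawall), multiplied by $P_{\text{current}\to c}$. The
quotas are claimed over `n_iterations` rounds (default 20): each round,
every transition in seeded random order claims its per-round share
(`ceiling(remaining / rounds_left)`) from the still-unassigned cells of its
source class where the destination is most suitable, ties broken by a
seeded uniform key. Static classes (water, ponds, roads, and cordgrass in
the no-invasion counterfactual) and nodata cells are copied unchanged.

Two design points deserve emphasis, because the allocation rule is the part
of CA-Markov that off-the-shelf implementations leave undocumented:

* *Iterations are allocation rounds, not simulated years.* The simulated
  span is a separate `n_years` argument; a 22-year simulation with the
  default configuration performs 22 steps of 20 rounds each. Reading the
  iteration count as years would make a multi-decade run impossible to
  express.
* *Claiming is per transition, not per class.* An earlier design let each
  class claim from any unassigned cell; persistence (own-class suitability
  near 1 inside a belt) then out-competed conversions, the belts stayed
  anchored to the landward edge, and the seepweed centroid drifted back
  landward once its area peaked. Claiming per transition lets
  seepweed→reed conversions select the landward belt edge (where reed
  frequency is high) and mudflat→seepweed conversions select the seaward
  edge, so the belts translate coherently seaward — the behaviour the
  centroid series of the real system shows — while demand accounting stays
  exact by construction.

The invader can be excluded from a simulation either by leaving its code
out of the matrix (it is then a static class, frozen in place) or by
recoding it to nodata before the run (masked, excluded from all
accounting); the package exposes both because they differ in the
denominator of area proportions.

## Validation

`cross_tabulate` computes the confusion matrix over all scheme classes
(reference map in rows — stated in every output header), overall accuracy
$p_o$, and Cohen's kappa $(p_o - p_e)/(1 - p_e)$ with $p_e$ from the
marginals. In the degenerate case $p_e = 1$ (both maps constant at the same
class) kappa is defined as 1 with a warning. The single-coefficient kappa
is implemented; location/quantity decompositions are out of scope.
`transition_matrix_between` converts the same cross-tabulation to hectares,
whose row and column sums reconcile exactly with the per-date class areas.

## Zonation geometry

The mean boundary distance follows $L = S/D$: for every baseline-parallel
column containing the class, the nearest (or farthest) class-cell centre
defines a per-column boundary distance; $D$ is the projected length of the
boundary on the baseline (occupied columns × cell size) — only occupied
columns enter, per the definition of a projection — and $S$ the enclosed
area, so $L$ is the column-mean boundary standoff and the identity
$L = S/D$ holds to machine precision by construction. The centroid is the
area-weighted mean perpendicular distance of all class cells — a 1-D
centroid, matching how belt positions are reported as single distances.
Movements between dates are signed seaward-positive, with rates per year.
Isolated outlier patches enter the boundary statistics; for band-like
classes $L_{near} \le$ centroid $\le L_{far}$, though cell-weighted
centroids of strongly non-banded shapes can escape that bracket, which is
why the bracket is a property of banded inputs, not an assertion of the
constructor. Percent changes are always relative to the earlier date and
ratios are reported separately, avoiding the ambiguity of mixed "%" and
"times" phrasings.

## The synthetic generator

`make_banded_grid` builds the land→sea belt sequence reed → seepweed →
(optional cordgrass strip) → mudflat, with any remaining seaward depth as
static water. Defaults are chosen once to mirror the observed 1985
composition of the study frame — band fractions 0.21 / 0.16 / 0.60 of grid
depth on 30 m cells — with boundary roughness 2 cells, a realistic ragged
front for a prograding silty shore. Boundaries are jittered by a
seeded Gaussian random walk along columns, rescaled to the requested
standard deviation and clipped so belt ordering is never inverted (keeping
nearest ≤ farthest well defined).

`evolve` is the ground-truth stochastic process: each dynamic cell
transitions with probabilities $(1 - w)P_{\text{cur},\cdot} + w f$, where
$f$ is the class frequency among dynamic cells in the 3 × 3 neighbourhood
and $w$ the contagion weight (default 0.25). The mixture form makes $w$
interpolate between the exactly analysable cell-independent Markov chain
($w = 0$, under which `estimate_transitions` provably recovers the
generating matrix to binomial error) and strongly spatial regimes. The
contagion neighbourhood is 3 × 3 rather than the CA's 5 × 5 filter: the
generator models local vegetative spread, not the allocator.

What the generator does *not* emulate: tides, sediment transport,
elevation or salinity gradients, the observed southward drift of river
mouths, classification error in the source imagery, and the sharp
anthropogenic geometry of aquaculture ponds. Passing tests on synthetic
data therefore demonstrate the correctness of the estimators, the
allocator's accounting and the metric geometry — not that the fitted model
captures every driver of the real coastline.

## Numerical choices

* Row-sum tolerance $10^{-9}$ for accepting a matrix as stochastic;
  renormalization window 0.01 for printed matrices.
* Largest-remainder rounding everywhere fractional cells must become whole
  cells; transportation repair for transition quotas.
* Seeds: every stochastic component (generator, evolution, allocator
  tie-breaks) takes an explicit integer seed and is byte-reproducible;
  `ca_run` seeds once and lets steps consume the stream, so a length-1 run
  equals a single `ca_step`.
* Degenerate inputs: empty source classes get identity rows; a class
  absent from a grid raises an explicit error from `boundary_profile`
  rather than NaN; zero jointly-valid cells is an error in validation.

## Problem sizes

The shipped analyses and tests use 200 × 200 to 300 × 300 grids (360–810
ha at 30 m), 22-year simulations, 100-seed agreement ensembles and
50-grid metric sweeps — sizes at which binomial recovery bounds are tight
and the whole suite runs in well under a minute, chosen as the package's
standard worked-example scale.

## Known limitations

* The allocator is one concrete, fully specified member of the CA-Markov
  family; proprietary implementations resolve the multi-objective conflict
  differently, so cell-level agreement with them is not expected even when
  area-level behaviour matches.
* Matrix roots of non-embeddable transition matrices are regularized by
  clip-and-renormalize; the reported residual should always be inspected.
* The published validation statistics of the original Yancheng study
  (accuracy 0.9152, kappa above 0.8 for the 1995 hindcast) require the
  original Landsat classifications, which are not redistributable; the
  package reproduces the method and its printed worked examples, and
  replaces map-specific results with property checks on synthetic data.
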