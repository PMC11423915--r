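---
title: "Quantitative morphometry of kelp embryo laminae: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative morphometry of kelp embryo laminae: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminamorph)
```

## The measurement problem

Early sporophytes of the kelp *Saccharina latissima* grow as flat
monolayers (laminae) of roughly cuboid cells arranged in rows and columns.
Severing the young embryo from the maternal stalk — the empty oogonium
wall that tethers it to the female gametophyte — changes how the embryo
establishes its body axes: blades grow rounder, cells become smaller and
less rectangular, tissue topology shifts, and longitudinal cell divisions
start far earlier than the 8-cell stage at which they normally appear.
Quantifying these phenotypes requires per-cell and per-blade geometry from
manually segmented cell-wall outlines, tissue topology from wall
adjacency, growth-rate estimation from time-lapse counts, and a small
battery of group-comparison statistics. This package implements that
chain, end to end, plus a synthetic-data module so that every stage can be
validated against known ground truth.

## Input model

A **lamina** is one embryo at one time point: a non-empty set of closed,
simple cell polygons in micrometres, with stage metadata. Segmentations
arrive as SVG: every closed `path`, `polygon` or `rect` element is one
cell; other elements are ignored with a warning, and an *open* tracing is
an error rather than a silent drop, because the cell count is itself a
measurement. Hand tracing yields one independent closed outline per cell,
so a wall shared by two neighbours appears twice; the package keeps both
copies and recovers adjacency geometrically (below). SVG's downward y axis
is flipped at ingest, contours are normalised counter-clockwise, and
consecutive vertices closer than 1e-9 µm (duplicate clicks) are merged.
Physical scale (µm per drawing unit) always comes from the caller or the
manifest, never from SVG metadata, which manual tracing tools do not
calibrate reliably.

## Per-cell descriptors

For each cell the package computes area and perimeter (shoelace formula),
the convex hull, and the **minimal bounding rectangle** (MBR) of the hull
by rotating calipers — the minimal-area enclosing rectangle has one side
collinear with a hull edge, so only hull-edge orientations need
examination. The cell's main axis, and its elongation (length/width
ratio), are those of the MBR. Ties in MBR area within 1e-12 relative are
broken by the smallest angle in [0, π), so a square cell deterministically
reports elongation 1 at angle 0.

**Rectangularity** scores how close a cell is to a rectangle with
perpendicular sides: the MBR is rescaled uniformly about its own centre to
the cell's area, and the score is

> R = area(cell ∩ rescaled MBR) / area(cell) ∈ (0, 1].

"Rescaled to the same area" admits two readings (shrink the rectangle or
inflate the cell); rescaling the MBR leaves the measured object untouched
and gives exactly 1 for any rectangle under either reading. The overlap is
clipped with an exact Sutherland–Hodgman pass against the (always convex)
rescaled rectangle in double precision; a perfect rectangle therefore
scores 1 to within 1e-9, not merely approximately. Area, perimeter,
elongation and rectangularity are invariant under rigid motions, and
rectangularity and elongation under uniform scaling — properties the test
suite asserts directly.

## Tissue topology

Two cells are **neighbours** when they share at least 200 nm of cell wall
(`min_shared = 0.2` µm, exposed as a parameter). Because duplicated
hand-traced walls are nearly but not exactly coincident, shared length is
measured with a separate *coincidence tolerance* (`proximity_tol`,
default 0.05 µm): the shared wall length between cells a and b is the
length of a's boundary within that distance of b's boundary, averaged
with the reverse measurement so the quantity is symmetric. The measure is
computed analytically: for each edge of a, the set of points within
tolerance of an edge of b is a capsule (slab plus two end disks), each
convex, so each contributes closed-form parameter intervals whose union is
measured exactly. Near a corner where two cells touch, the capsule picks
up ~2×tolerance of the perpendicular walls; at 0.05 µm this is far below
the 0.2 µm edge criterion. Candidate pairs are pruned by bounding boxes
expanded by the tolerance, which provably cannot change the result; the
tests compare pruned against brute-force all-pairs construction.
Neighbour counts are summarised over the bins {1, 2, 3, 4, ≥5} used for
the topology contrasts: on a clean rectangular tessellation, corner cells
have 2 neighbours, peripheral cells 3, internal cells 4.

## Blade-level geometry

The blade region is the union of all cell polygons (through polyclip), so
slight tracing overlaps never double-count. Blade orientation comes from
the second-order area moments of the union region (principal-axis
decomposition, with the angle snapped to 0 when the moments are isotropic
to within 1e-6, as in a square blade where orientation is undefined);
blade length and width are the extents of the region projected onto the
two principal directions, and the blade l/w ratio is their quotient. The
developmental windows used to compare groups independently of growth
delay are closed cell-count bins: [20:47], [48:103], [104:307]; anything
else is "other".

A division plane is classified relative to the blade main
(apico-basal) axis after folding the relative angle into [0°, 90°]:
**longitudinal** within `oblique_band` (default 30°) of parallel,
**transverse** within the same band of perpendicular, **oblique**
otherwise. The band is configurable because the source analyses report
only parallel and perpendicular planes without stating bins; 30° splits
the quadrant evenly.

## Growth rate

Cell counts follow N(t) = N₀·r^t. Each embryo's clock is set to t = 0 at
the phase I → II transition (first longitudinal division, a flag carried
by the series, not inferred from geometry); ordinary least squares of
log N on t over the inclusive window −48 h ≤ t ≤ 72 h gives log r as the
slope, and the doubling time is τ = 1/log₂(r) = ln 2 / slope. Natural
logs are used internally; the result is basis-independent. Slopes below
1e-12 h⁻¹ are numerical noise on a flat series and report τ = ∞ with a
warning; group summaries average finite τ and log how many infinities
they dropped. Fits are per embryo, then averaged per group — the source
does not state whether embryos were pooled before regression, and
per-embryo fitting keeps embryo-to-embryo dispersion visible.

## The synthetic-data module

Because the study's raw segmentations are not deposited, the generators
are first-class, tested code whose defaults encode the study conditions.

**Grid laminae** (`generate_lamina`): a rows × cols tessellation of
quadrilaterals with *shared* vertices, so the tessellation is a partition
— duplicated walls coincide exactly and the blade union equals the sum of
cell areas analytically. `jitter` displaces each grid vertex once by a
uniform fraction (< 0.5, which precludes edge crossings) of the cell size,
degrading rectangularity without breaking the partition.
`elongation_target` applies an area-preserving anisotropic stretch, so
blade l/w hits the target while mean cell area stays `cell_size²`; the
study's blades span l/w ≈ 1–3.5. An elliptical mask emulates rounded
outlines. Every generator output carries analytic ground truth (cell
areas and perimeters from the construction arithmetic, grid adjacency
with exact wall lengths, blade axes) computed without touching the
analysis code.

**Division simulator** (`simulate_division_growth`): an event-driven
birth process on an integer lattice. Cycle times are gamma distributed
with mean 26 h — the study's mean division interval — and coefficient of
variation 0.25 by default; a modest spread is what real, loosely
synchronised cell populations show, and by the Euler–Lotka relation a
gamma spread of CV 0.25 keeps the population doubling time within ~3% of
the mean cycle time, so fitted τ should recover ≈ 26 h. (With
exponential cycle times the population doubles every ln 2 × 26 ≈ 18 h —
a Yule process — which is why the simulator does not default to them.)
The first division is always transverse, in both modes. Longitudinal
divisions are forbidden below 8 cells in intact mode and below 2 cells in
severed mode, and once permitted are drawn with probability 0.3 (intact)
versus 0.5 (severed): the maternal signal in the study *represses*
longitudinal division throughout early embryogenesis rather than
switching off at 8 cells, and a persistent transverse bias is required
for intact blades to stay elongated at the 100-cell stage while severed
blades grow round — with 0.5 in both modes, the 8-cell head start washes
out and no blade-shape phenotype survives. Geometrically, a division
inserts a lattice line (shifting cells beyond it) or reuses a free
adjacent slot; snapshots are rendered by dropping empty apico-basal tiers
and stacking each tier contiguously about the midline, which yields
hole-free monolayers whose periphery/interior split is meaningful. The
simulator reproduces the *direction* of the published phenotypes (intact
blades more elongated; a higher share of 3-neighbour peripheral cells in
intact, more 4-neighbour internal cells in severed) but is not fitted to
their magnitudes — simulated intact blades overshoot the published l/w
because every transverse division extends the full apico-basal axis,
and no mechanical relaxation is modelled.

**Parametric growth series** (`generate_growth_series`): exact
exponential expected counts, optionally with multiplicative log-normal
noise (a running maximum restores monotonicity, since cells cannot
merge). Noiseless series recover their doubling time to machine
precision, which pins the regression algebra; noisy series are for
calibration-style tests. Expected counts are real-valued by design; the
division simulator is the integer-count generator.

All generators take a seed, restore the caller's RNG state, and produce
byte-identical SVG output for identical seeds.

## Statistics

The comparison battery mirrors the study's usage: per-cell scalars
(area, rectangularity, elongation), pooled across embryos within a
window, are compared with Welch's unequal-variance t test; per-blade
scalars (l/w ratio, blade area), with 4–6 embryos per group, with the
two-sample Mann–Whitney rank test (the "Wilcoxon" of some figure legends
is the same rank test family); neighbour-count bins with Pearson's χ²
without Yates correction, dropping bins empty in all groups with a
warning. All tests are two-tailed. The Mann–Whitney implementation
enumerates the exact null when the combined sample is ≤ 12 without ties
(the regime of the blade comparisons) and otherwise uses the midrank
normal approximation with continuity correction. No multiple-testing
correction is applied, matching the source analyses; the pipeline reports
the number of comparisons performed so a reader can judge. The binomial
sample-composition check computes (1−p)ⁿ and n·p — with the published
background abnormality frequency p = 0.04781 and n = 5 it returns 0.78
and 0.24.

```{r}
binomial_composition(0.04781, 5)
```

## Numerical choices

Geometric predicates use an absolute tolerance of 1e-9 µm, far below
tracing precision (~0.1 µm). Polygon boolean operations for the blade
union go through polyclip (integer-snapped at ~1e-9 relative, negligible
for areas); the rectangularity overlap deliberately avoids that snapping
via exact clipping so rectangles score exactly 1. Degenerate inputs fail
loudly with the offending cell named: zero-area polygons, self-crossing
outlines, collinear hulls, growth series with fewer than three in-window
points.

## What the tests do and do not show

The suite validates the measurement chain against independent oracles:
Monte Carlo integration for areas and overlaps, an O(n³) half-plane test
for hulls, a dense angle sweep for the MBR, dense boundary sampling for
shared walls, exhaustive enumeration for the exact Mann–Whitney null and
the binomial composition, a 2,000-replicate null simulation for Welch
calibration, and the generators' analytic ground truth. Problem sizes
(10⁶ Monte Carlo samples, 10⁵-step angle sweeps, 100-cell simulations,
20-seed replicate sets) were chosen to make the oracle comparisons sharp
at ordinary desktop runtimes. What passing tests show is that the
geometry, topology, regression and statistics are computed correctly and
that the simulated phenotypes move in the published directions. They do
not show that the generators reproduce real tracing noise — hand-traced
walls have correlated, curvature-dependent errors that uniform vertex
jitter does not emulate — nor that simulated effect magnitudes match real
embryos, and the division simulator makes no claim about mechanics, cell
growth, or oblique divisions (observed rarely in severed eggs, never
generated here).

## Known limitations

- Curved cell walls are not supported at ingest; tracings must be
  polygonal (curve commands in SVG paths are rejected, not sampled).
- The blade main axis is the operational apico-basal axis; the stalk
  position, absent from segmentations, is never used as a landmark.
- Shared-wall measurement near corners includes ~2× the coincidence
  tolerance of perpendicular wall; irrelevant at the default settings
  but visible if `proximity_tol` is pushed toward `min_shared`.
- Lineage tracking across time points, 3-D geometry, and raster
  segmentation are out of scope.
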