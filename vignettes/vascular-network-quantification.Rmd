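---
title: "Quantifying whole-organ arterial networks from spatial graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-organ arterial networks from spatial graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctree)
```

## The data model

An arterial network extracted from a volumetric scan is represented here
as a *spatial graph*: nodes (branching points or terminal ends), segments
(node-to-node vessels), and ordered centreline points with per-point radii.
The interval between consecutive points is a sub-segment; every geometric
quantity is accumulated over sub-segments. Coordinates are world
micrometres. Storage is undirected: flow direction is derived at analysis
time from a root node — physiologically, the cut end of the feeding
artery, chosen as the terminal node attached to the thickest segment.

Raster data (intensity volumes, binary vessel masks, zone labels) are
isotropic 3D arrays indexed `[x, y, z]`, 1-based, with
`world = (index - 1) * voxel_size + origin` at voxel centres. This is the
natural convention for base R arrays; writers and readers translate to
the 0-based conventions of foreign formats at the boundary.

## Ordering and scaling laws

Strahler ordering is centripetal: terminal segments are order 1; where
two children of equal order meet, the parent is one order higher,
otherwise the larger child order propagates. At junctions with more than
two children we use the standard generalisation — the parent increments
iff at least two children attain the maximum. Degree-2 passthrough nodes
are transparent to both orderings, which makes the orders invariant under
segment subdivision (a property the test suite checks). Topological
generations are centrifugal: the root segment is generation 1 and every
true branching node increments the label.

The branching ratio $\gamma$ is estimated from the per-order segment
counts $N(O)$ by ordinary least squares of $\ln N$ on $O$, with
$\gamma = e^{-\text{slope}}$: the factor by which segment counts multiply
per order step. On the published per-order counts of the whole human
kidney arterial tree this yields $\gamma \approx 2.92$. We note that the
decay-law display equation in the source literature is typeset with
$\gamma$ in the exponent's rate position; read literally that would make
$\gamma$ a natural-log rate near 1.07, irreconcilable with the printed
ratio of 2.921. We therefore implement the only reading that reproduces
the printed value, $N \propto \gamma^{-O}$.

Murray's law states that at an energy-optimal bifurcation
$R_\text{parent}^3 = \sum_i R_i^3$. Each junction contributes one point
$x = (\sum_i R_i^3)^{1/3}$, $y = R_\text{parent}$, and an ordinary
least-squares line is fitted after robust outlier removal; the
theoretical law is the identity line in any units. Regressing radii
rather than cubed radii bounds the leverage of the few largest vessels; a
`on_cubes = TRUE` variant is provided. The default unit scale converts
micrometres to metres before fitting, the scale on which organ-level
intercepts are conventionally reported.

Outlier removal approximates robust-regression-with-FDR at rate
$Q = 0.05\%$: a least-absolute-deviations line (iteratively reweighted
least squares), residual scale from the 68.27th percentile of absolute
residuals, t-like statistics, and a Benjamini–Hochberg step at rate $Q$.
The exact internals of the proprietary implementation used in commercial
statistics software are not public; this approximation preserves its two
contract properties — exact-line data are never trimmed and $Q = 0$
removes nothing — but is not bit-identical to it.

Nested models (single global slope/intercept versus per-dataset fits) are
compared with the extra sum-of-squares F test,
$F = \frac{(SS_0 - SS_1)/(df_0 - df_1)}{SS_1/df_1}$.

## Morphometry conventions

* **Tortuosity** is path length / chord length ($\ge 1$). The methods
  prose of the source study words the ratio the other way around, but its
  reported tables carry values of 1.1–1.2, so the implemented orientation
  follows the numbers; `literal_tortuosity = TRUE` gives the reciprocal.
* **Length:radius ratio**: the published per-order table matches
  length/radius (order-1 row: 2600/45 ≈ 57.8 against a printed 57.4), not
  length/diameter as its column label suggests; the default is
  length/radius with `ldr_uses_diameter = TRUE` as the alternative.
* **Sub-segment radius** is the mean of its two endpoint radii, and
  segment volume sums one cylinder per sub-segment — the definition that
  reproduces the published order-9 row (volume $\approx \pi r^2 L$ within
  rounding). The published volume column is internally inconsistent for
  middle orders (rows 3–4 are an order of magnitude above
  $\pi \bar r^2 \bar L$); we keep the definition validated on the
  consistent rows.
* **Branching angles** use segment chords (start to end node), ignoring
  tortuosity, each vector pointing away from the junction; a straight
  continuation scores 180°. All child pairs are reported at junctions
  with more than two children.
* **Inter-vessel distance** comes in two forms: nearest-neighbour
  distance between segment midpoints (half cumulative path length,
  interpolated), excluding only the segment itself by default; and the
  voxel-wise exact Euclidean distance transform of the vessel mask,
  summarised per anatomical zone when labels are given.

## Skeleton correction

Large vessels several voxels wide emerge from skeletonization with
jagged centrelines; vessels whose lumen collapsed during preparation
carry artifactually small radii.

* **Multiscale smoothing** (orders ≥ 6 by default) replaces each interior
  point by a Gaussian-weighted average over an arc-length window of twice
  the local radius, then applies only the component of the displacement
  normal to the local tangent. Endpoints are anchored, radii untouched,
  topology exactly preserved; straight polylines are exact fixed points,
  and the total turning angle of a jagged line strictly decreases.
  The order threshold follows the study's methods prose ("greater than
  5"); its pipeline figure prints both readings, so the threshold is
  configurable.
* **Collapse detection** flags, within each order of at least 20
  segments, the segments whose mean radius falls below the order's lower
  10th percentile. The source figure describes outliers "below the 90%
  percentile", which read literally would flag 90% of all segments; the
  sparse outliers it displays make clear a lower-tail rule is meant, so
  the percentile (default 10) is an explicit parameter feeding a
  confirmation step — against the generator's ground-truth manifest here,
  by a human in the original workflow.
* **Radius restoration** extracts, at every centreline point of a
  confirmed segment, the plane normal to the local tangent, finds the
  mask component at the projected point, and assigns the equivalent
  radius $P / 2\pi$ from the component's perimeter. Corrected radii
  replace the per-point radii (the segment mean is then recomputed by the
  metrics layer); points whose plane misses foreground keep their radius
  and are flagged.

## Numerical choices in the raster layer

* **Distance transform**: exact Euclidean, separable lower-envelope
  algorithm, validated against brute force on all test masks.
* **Cross-sections** are sampled with deterministically chosen in-plane
  axes (smallest-|component| world axis crossed with the tangent), so
  sections are reproducible bit for bit. Binary volumes are sampled
  nearest-neighbour to keep labels crisp.
* **Perimeter of a digitised section component**: the default estimator
  takes the convex hull of the component's pixel centres and adds a
  Steiner offset $2\pi\delta$ with $\delta = 0.4$ px for the half-pixel
  inset of centres relative to the digitised boundary. Measured errors
  are +1.0% on a radius-20 disc, −1.9% on an aligned square, −0.7% on a
  45°-rotated square and +0.4% on a 10:1 ellipse, and the estimate varies
  under 1% under sub-pixel translations. The raw marching-squares
  iso-contour length is available as `method = "contour"`, but on binary
  inputs its staircase overestimates smooth boundaries by ≈5%, which is
  why it is not the default. The hull estimator assumes a convex (or
  near-convex) section, which holds for open and collapsed vessel lumens;
  for strongly concave components it overestimates, a documented
  limitation. A single-pixel component returns $2\pi\delta$ times the
  pixel spacing by convention.
* **Skeletonization** (validation plumbing only) is sequential thinning
  by simple-point removal with six directional sub-iterations per sweep
  (a voxel is deletable from direction $d$ only while its opposite face
  neighbour is foreground, so a sub-sweep cannot tunnel through thin
  structures), endpoint preservation, and distance-ordered processing.
  Spur branches seeded by surface bumps are then removed by iterative
  erosion of prunable voxels (those whose neighbours form a single
  connected component and whose removal is topologically simple) for
  twice-the-maximum-depth rounds: spur length is bounded by the local
  vessel radius, so spurs vanish while real branches only shorten.

## Validation metrics

Topological precision and recall thin both masks and measure the
fraction of each skeleton within a voxel tolerance of the other mask —
centreline overlap rather than volumetric overlap. An empty prediction
reports precision 0 with a flag rather than erroring, so batch sweeps
complete.

The five-term skeleton super-metric compares a reconstructed spatial
graph against a reference segmentation: relative network-volume deviation
(the skeleton re-voxelized with its radii), connected-component count
deviation, Euler-characteristic deviation, centreline sensitivity
(fraction of skeleton points inside the mask) and bifurcation DICE
(greedy nearest-pair matching of branch points within a tolerance radius,
deterministic under distance-then-index ordering). The mask-side Euler
characteristic is computed on the cubical complex of the thinned mask
($\chi = V - E + F - C$ over distinct vertices, edges, faces and cubes),
which is immune to the spurious triangles that a naive 26-adjacency voxel
graph contains along staircase paths. Mask-side branch points are voxels
whose surrounding radius-3 box contains three or more skeleton strands
reaching the box boundary. The published work does not print its term
weights, so defaults are equal weights, echoed in the result. On
self-comparison (a synthetic tree against its own voxelization) every
term vanishes for well-separated branching angles; where two child
vessels leave a junction at a shallow mutual angle their capsules merge
and the voxel skeleton genuinely bifurcates downstream of the graph node
— a resolution limit of voxelized skeletons, not of the matcher.

## Zonal analysis

Zone membership samples each centreline point at its containing voxel of
the label volume. A segment is assigned to a zone only if its points are
unanimous; any boundary contact makes it "crossing", excluded from zone
rows but kept in the organ totals — the reading most consistent with the
convention that segments crossing two regions are excluded, and the
reason zone segment counts sum to less than the organ count. A
majority-rule option exists. Centreline sampling (rather than the full
lumen) is our choice and is documented as such.

## The synthetic generator

`generate_tree()` grows a rooted tree whose defaults emulate the
architecture reported for the whole human kidney arterial network: depth
9 (nine Strahler orders), a target branching ratio of 2.9 (realised by
random trifurcation with probability 0.9, so the realised ratio is an
emergent, seed-dependent quantity), root radius 2.9 mm, Murray-law radii
at bifurcations with configurable asymmetry, chord lengths proportional
to radius, and a sinusoidal centreline perturbation whose default
amplitude (0.65) yields per-segment tortuosity near 1.1. Child directions
are drawn in a cone (default half-angle 40°) about the parent direction
with evenly spread azimuths; candidate tips colliding with existing nodes
are re-sampled up to a retry cap. `perturb_graph()` injects centreline
jitter, radius noise, collapsed segments (radius scaling with a recorded
ground-truth manifest) and terminal-branch deletions that can never
disconnect the root component. `voxelize()` renders a graph as a union of
linearly interpolated capsules; `generate_zone_phantom()` builds nested
spherical cortex/medulla/hilum compartments with optional azimuthal
pillar wedges.

What the generator does *not* emulate: imaging noise and contrast
gradients, vessel walls (only lumens), anastomoses or venous return,
spatially varying branching statistics, and the anatomically lobed
geometry of real kidney compartments. Passing tests therefore demonstrate
the correctness of the measurement chain on networks with known ground
truth, not the fidelity of any segmentation of real scan data.

## Problem sizes and determinism

The test suite runs entirely on synthetic data: trees up to depth 9
(≈500–9000 segments), masks up to roughly 300³ voxels for the
voxelization and super-metric fixtures, and brute-force oracle sweeps on
masks up to 16³. These sizes were chosen so that each oracle can be
computed exactly and the whole suite stays interactive. All stochastic
fixtures are seeded; `run_pipeline()` hashes its configuration, and
identical configuration plus seed reproduces outputs byte for byte.

## Known limitations

* The deposited whole-organ arterial graph is not redistributable with
  the package; the acceptance test that reproduces its published totals
  runs only when the file is placed under `inst/extdata/`.
* Cyclic graphs are rejected by the ordering layer by design (arterial
  trees are acyclic); anastomotic networks would need a different
  ordering scheme.
* The perimeter estimator assumes near-convex sections (above).
* Bifurcation matching in the super-metric is limited by capsule overlap
  at shallow branching angles (above).
* Volumes are processed in memory; organ-scale rasters at full
  resolution are out of scope.
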