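---
title: "From voxels to circuits: methods behind skelemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From voxels to circuits: methods behind skelemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelemorph)
```

skelemorph turns a voxel segmentation of a single neuron into a centerline
skeleton and carries that skeleton through morphometric, similarity and
connectivity analysis. This vignette explains the model behind each stage,
the parameters that matter, the numerical conventions the package fixes,
and what the synthetic test surfaces do and do not establish about real
data.

## Coordinates, masks and the distance field

A `seg_chunk` is a 3D array of object IDs with an anisotropic voxel size in
nanometers (electron-microscopy stacks are commonly much coarser along the
cutting axis, e.g. 5 x 5 x 45 nm). Voxel indices are 0-based and global;
the physical position of a voxel is `(index + 0.5) * spacing_nm`, i.e. the
voxel *center*. Centering makes phantom ground truth exact: a tube of
radius r voxels contains precisely the centers within r of its axis.

One object's occupancy is bit-packed (`pack_mask`) at 1 bit per voxel — an
8-fold saving over byte masks, which matters when a single neuron spans
hundreds of chunks. The payload layout is part of the format and therefore
fixed: x-fastest linearization, little-endian bit order within each byte.

`compute_dbf` computes the distance-from-boundary field (DBF): for every
foreground voxel, the anisotropic Euclidean distance to the nearest
*background voxel center*. Two conventions had to be chosen because
distance transforms differ between implementations:

* distance is measured center-to-center (the standard Euclidean distance
  transform convention), not to the nearest face;
* everything outside the mask's bounding box, padded by one voxel, counts
  as background, so objects touching the chunk border still get a finite
  positive DBF.

The transform itself is the separable lower-envelope algorithm applied per
axis with squared per-axis spacings, which handles anisotropy exactly; the
test suite checks it voxel-for-voxel against an exhaustive nearest-background
search on masks up to 16^3.

## TEASAR-style centerline tracing

The tracer works on the 26-connected graph over foreground voxels. The
cost of stepping onto voxel `v` is

    ||pos(u) - pos(v)|| + penalty_scale_nm * (1 - dbf(v) / dbf_max)^penalty_exponent

so the adjacency is undirected but costs are directed arcs: moving *onto* a
near-boundary voxel is expensive, moving along the medial axis is nearly
free. The defaults (`penalty_scale_nm = 5000`, `penalty_exponent = 16`)
follow the classic center-hugging penalty: with exponent 16 the penalty is
negligible for voxels in the inner half of the object and grows steeply in
the outer tenth, and 5000 nm dwarfs any single physical step so paths never
cut corners through the boundary region. Both are exposed because the right
scale depends on process caliber relative to voxel size.

Tracing proceeds per connected component:

1. seed at the maximum-DBF point (ties broken by lowest lexicographic voxel
   index — one of several small determinism rules; the whole trace consumes
   no random numbers and identical inputs give bit-identical skeletons);
2. build the penalized shortest-path tree from the seed (Dijkstra, via
   igraph);
3. repeatedly take the farthest unvisited voxel (penalized graph distance)
   as the destination, walk the predecessor chain back, and stop at the
   first already-skeletonized node — that node is the attachment point;
4. mark every point within `max(invalidation_scale * dbf(n),
   invalidation_min_nm)` of a new path node as visited, and stop when
   nothing is left.

A design point worth recording: an alternative formulation re-seeds each
round at the unvisited point closest to the visited set and re-runs
Dijkstra from there. We implemented and rejected it — with per-round
re-rooting, the paths serving different limbs of a junction attach at
scattered nodes a few voxels apart, so a clean Y acquires two branching
nodes instead of one. Keeping a single shortest-path tree per component
funnels every limb through the same attachment and recovers junction
topology exactly; it is also cheaper (one Dijkstra per component).

The invalidation radius scales with local caliber (`invalidation_scale = 3`
with a floor of twice the finest spacing): thick trunks invalidate widely
so parallel spurious paths are not traced, while thin processes keep a
small radius so nearby genuine branches survive.

Node radius is the DBF at the node's voxel, and each component's tree is
rooted at its largest-radius node — a soma proxy, since the cell body is
the thickest structure of a complete neuron. Segmentation splits are healed
by `reconnect_components`: while at least two trees remain and the
globally nearest terminal-or-root pair across trees is within
`reconnect_threshold_nm` (default 5000 nm), that gap is bridged, smallest
gap first, re-rooting the absorbed tree at its end of the bridge.

## Cleanup

`postprocess` applies six operations in a fixed order; each is idempotent
on its own output and preserves the forest invariants:

1. **redundant-node removal** — consecutive nodes along a segment closer
   than `redundant_eps_nm` merge, keeping the larger radius. The default
   resolves to the finest voxel spacing: anything closer than one voxel is
   discretization noise, not structure.
2. **hair removal** — a terminal segment hanging off a branching node is
   deleted when its path length is under `hair_ratio` (1.5) times the
   attachment node's *diameter*. TEASAR-family tracers grow such whiskers
   toward surface bumps whose size scales with local caliber, hence a
   diameter-relative threshold; 1.5 removes them while leaving any genuine
   branch that escapes the parent's own volume. Segments attached directly
   to the root are exempt so a stubby neuron cannot be shaved to a point.
3. **soma-branch removal** — the root is the soma proxy; any maximal
   subtree lying entirely within the sphere of the root's radius is an
   artifact of tracing the soma's interior and is deleted. Branches that
   exit the sphere are kept whole.
4. **resampling** — each segment is re-parameterized by arc length at
   `resample_spacing_nm` (default 500 nm, about the node density of
   manually traced morphologies); irreducible node positions are preserved
   exactly and radii interpolate linearly. A segment shorter than the
   spacing keeps only its endpoints.
5. **empty-branch removal** — zero-length terminal segments (a child chain
   coincident with its branch node) are dropped. "Empty" is read as
   zero-*length* rather than zero-voxel-support, since voxel support is no
   longer known at this stage.
6. **smoothing** — a centered moving average (odd `smooth_window`, default
   3) over segment interiors; endpoints are pinned, and near an endpoint
   the window shrinks symmetrically so the filter stays unbiased.

## SWC, text and binary

Skeletons serialize as standard 7-column SWC (`id type x y z radius
parent`, `#` comments, parent `-1` for roots), in nm, the dataset-native
unit. For bulk work there is a binary twin: little-endian `uint32` node
count, then 28-byte records of `int32 id, int32 type, float32 x/y/z/radius,
int32 parent`. The layout is bit-exactly specified above because it *is*
the format; no compatibility with any other binary SWC dialect is claimed.
Round trips are exact in text and float32-exact in binary, and the suite
checks both codecs agree.

## Morphometrics

`decompose_skeleton` cuts a tree at every irreducible node (root, branching
node, terminal) into maximal unbranched segments; orders count up from the
root. Per segment: path length; tortuosity (path over chord between the
segment's endpoints, undefined for zero chord and reported as `NA`); path
distance to the root; mean radius; the branching angle at its distal node
(mean over daughter pairs of the angle between unit vectors toward each
daughter's *distal* irreducible node — pointing at the distal node rather
than the first child node makes the angle robust to node jitter right at
the junction); and, for terminal segments, the neck/head radius ratio used
as a spine signature, splitting the segment at its arc-length midpoint
(minimum radius proximal, maximum distal) since no principled split point
is available without a spine model.

Per neuron, `neuron_features` aggregates: total path length, branching
point count, median and longest segment length, mean branching angle and
tortuosity, a Sholl profile (edge crossings of concentric spheres centered
on the root, nodes exactly on a sphere counted once), asymmetry (distance
from the root to the unweighted node center of mass), typical radius (RMS —
not mean — distance of nodes to the center of mass, consistent with a
radius of gyration), box-counting fractal dimension, convex hull volume,
frustum surface area (`pi * (r1 + r2) * slant` per edge), and pre/post
synapse counts when a synapse table is supplied.

Fractal dimension uses dyadic box sizes from half the largest extent down
to 1/64 of it and the least-squares slope of `log N` vs `log(1/s)`; it is
reported as `NA` below 32 points or at zero extent, where the slope is
meaningless. The convex hull is computed by an incremental quickhull-style
insertion written in R (no installed package provides 3D hulls here);
degenerate inputs — fewer than four distinct points, collinear or coplanar
sets — return volume 0, and face visibility uses a tolerance of `1e-9`
times the cubed bounding-box extent so the classification scales with the
data.

## NBLAST similarity

`make_dotprops` resamples a skeleton to ~1 um spacing, converts to um, and
takes as tangent at each point the dominant principal axis of the point and
its k = 5 nearest neighbors (sign-free). The raw score of query against
target sums, over query points, a score function of the distance to the
nearest target point and the absolute tangent dot product. The default is
the parametric kernel `adp * exp(-d / sigma_um)` with `sigma_um = 3` — a
3 um decay matches the scale at which neighboring neurites of the same
cell type track each other — and published tabulated score matrices can be
loaded from CSV (`read_score_function`) as a drop-in replacement.

Scores normalize by the query's self-score, so the forward matrix has unit
diagonal; the symmetrized matrix averages the two directions. Both views
are kept (`normalized` is the forward score, `symmetrized` the mean) and
the mean is the default for clustering, which runs average-linkage
agglomeration on `1 - symmetrized` and cuts to a requested number of
types. Cutting by count rather than height is a choice: type counts are
what downstream circuit analyses consume.

## Connectivity and its relation to morphology

A synapse table (CSV; detection happens upstream) becomes a directed
count matrix `counts[i, j]` = synapses from i onto j, autapses on the
diagonal, rows with unknown ids dropped and logged. The symmetrized count
`s_ij` maps to a distance `1 / (1 + s_ij)` — any monotone decreasing map
onto (0, 1] encodes "more synapses, closer"; this one is bounded, metric-
like and parameter-free. Communities come from average-linkage clustering
of that distance, and the matrix can be reordered by either its own
dendrogram or by morphological (NBLAST) cluster labels to put putative
types in blocks.

The morphology–connectivity relationship is quantified as the Spearman
rank correlation, over unordered neuron pairs, between symmetrized NBLAST
score and symmetrized synapse count, with a permutation p-value (>= 999
shuffles of neuron identity). A permutation test is used because matrix
entries sharing a neuron are not independent, so a parametric p-value for
the correlation would be anti-conservative.

## The synthetic module: what it emulates and what it does not

Every stage above is exercised end to end on generated data with exact
ground truth:

* voxel phantoms — solid tubes (`make_cylinder`, with foreground within
  10% of `pi r^2 L`), junctions (`make_y`), fragmented tubes with a known
  gap (`make_broken_tube`), stars with n terminals (`make_star`), and a
  sphere-with-neurites soma model (`make_soma_with_neurites`); each records
  its centerline, branch point, gap or soma geometry in nm;
* circuits — `make_circuit` places per-class archetype skeletons in
  spatial territories 150 um apart with distinct bends, applies Gaussian
  node jitter (sigma 2 um by default; Gaussian because it gives analytic
  control over NBLAST separability), and draws each ordered pair's synapse
  count as Poisson with rate 8 within a class and 0.5 across classes.
  Those rates put within-class pairs at ~16 expected symmetrized synapses
  against ~1 across classes — strong, clean community structure.

These surfaces verify the machinery, not biology: phantoms have constant
caliber, no noise on the segmentation boundary, and gaps are clean cuts;
circuit archetypes are single unbranched arbors, jitter is isotropic, and
synapse placement ignores arbor geometry. Passing tests therefore
demonstrate correctness of the algorithms under their stated conventions —
they do not calibrate parameters for any particular imaging pipeline, and
real segmentations (merge/split errors, variable caliber, touching
neurites) will exercise the parameters in ways the phantoms do not.

Problem sizes in the shipped tests and acceptance script — 100 x 11 x 11
voxel tubes, 18-to-40-neuron circuits, 20 replicate seeds — were chosen as
the smallest sizes at which every planted structure is recovered exactly
and the stochastic checks have comfortable margins.

## Known limitations

* Sparse, per-object skeletonization only; densely skeletonizing every
  object of a volume at once is out of scope.
* The exact penalty functional of other TEASAR implementations varies;
  ours is the documented form above, so node-for-node agreement with other
  tools is not expected.
* No interactive skeleton editing, no registration to a template space,
  and no training of NBLAST score matrices from matched pairs — published
  tables can be loaded instead.
* Dendrite/axon compartment labels are accepted (SWC `type`) but never
  inferred.
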