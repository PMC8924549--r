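# skelemorph

Automated electron-microscopy segmentation labels voxels; quantitative
neuroanatomy needs trees. skelemorph bridges that gap for single (sparse)
neurons in R: it extracts centerline skeletons from labeled volumes,
cleans them, and carries them through single-cell morphometrics,
NBLAST-style similarity and clustering, and synaptic-connectivity analysis
— one consistent environment for connectomics desk work, tested end to end
on synthetic phantoms with exact ground truth.

## What it computes

* **Skeletonization** (TEASAR family). For one object: bit-pack the mask
  (1 bit/voxel), extract the foreground point cloud, compute the
  anisotropic distance-from-boundary field (DBF), then trace iterative
  shortest paths over the 26-connected voxel graph with the
  center-hugging step cost

  `w(u -> v) = ||pos(u) - pos(v)|| + s * (1 - dbf(v)/dbf_max)^p`

  (defaults `s = 5000` nm, `p = 16`), seeded at the DBF maximum, with
  caliber-scaled invalidation (`r = max(3 * dbf, 2 * min spacing)`). Node
  radius = DBF; fragments reconnect across gaps below a threshold.
* **Cleanup**: redundant-node merging, hair removal (terminal segments
  shorter than 1.5x the attachment diameter), soma-branch removal,
  arc-length resampling, empty-branch removal, smoothing.
* **SWC I/O**: standard 7-column text plus a compact little-endian binary
  layout (`uint32` count, 28-byte records), lossless round trips.
* **Morphometrics**: segment decomposition with orders; path length,
  tortuosity, branching angles, distance to root, neck/head ratio; per
  neuron: Sholl profiles, asymmetry, typical (RMS) radius, box-counting
  fractal dimension, convex hull volume, frustum surface area, synapse
  counts.
* **NBLAST**: dotprops (points + PCA tangents), score
  `sum adp * exp(-d / sigma)` (or a tabulated score matrix from CSV),
  self-score normalization, symmetrization, average-linkage clustering
  into morphological types.
* **Connectivity**: directed synapse-count matrices from CSV tables,
  distance `1 / (1 + s_ij)`, community clustering and matrix reordering,
  and a permutation-tested Spearman correlation between morphological
  similarity and synapse count.
* **Synthetic module**: cylinder / Y / broken-tube / star / soma phantoms
  with exact centerlines, and circuits with planted morphology classes and
  Poisson block connectivity — every algorithm above is testable without
  any imaging data.

## Worked example

```r
library(skelemorph)

## a solid tube, radius 4 voxels, length 100 voxels, 1 nm spacing
ph <- make_cylinder(length_vox = 100, radius_vox = 4, spacing_nm = c(1, 1, 1))
sum(ph$chunk$labels == 1)          # 4900 foreground voxels (~ pi r^2 L)

mask  <- pack_mask(ph$chunk, 1)
length(mask$bits)                  # 1543 bytes for 12342 voxels: 8-fold packing
cloud <- compute_dbf(mask)
range(cloud$dbf_nm)                # 1.0 .. 4.12 nm (boundary .. axis)

skel <- trace_skeleton(cloud)
skel
#> <skeleton> 96 nodes, 1 tree(s), total path length 96.7 nm
skel <- postprocess(skel, postprocess_params(resample_spacing_nm = 5,
                                             redundant_eps_nm = 1))
skel
#> <skeleton> 20 nodes, 1 tree(s), total path length 95.9 nm
```

The traced axis deviates from the true centerline by 0.28 voxels on
average, and the 95.9 nm path length is within 5% of the 100 nm truth
(nodes sit at voxel centers, so half a voxel is lost at each end).

```r
## similarity + connectivity on a synthetic 40-neuron, 3-class circuit
circ <- make_circuit(n_neurons = 40, n_classes = 3, seed = 7)
sim  <- nblast_matrix(lapply(circ$skeletons, make_dotprops))
cl   <- nblast_cluster(sim, n_clusters = 3)
mclust::adjustedRandIndex(cl$labels, circ$labels)
#> [1] 1

m <- build_connectivity(circ$synapses, names(circ$skeletons))
morphology_connectivity_association(sim, m, n_perm = 999, seed = 1)[1:2]
#> $rho
#> [1] 0.653785
#> $p_value
#> [1] 0.001
```

The clustering recovers the three planted morphological types exactly
(adjusted Rand index 1), and the planted coupling between class identity
and synapse rate surfaces as a positive Spearman correlation with a
permutation p of 0.001.

A batch command-line front end is installed as `exec/skelemorph`
(subcommands `skeletonize`, `features`, `nblast`, `connect`, `phantom`;
YAML config, `--seed` for anything stochastic).

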