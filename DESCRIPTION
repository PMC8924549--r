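Package: skelemorph
Title: Sparse Skeletonization, Morphometry and Synaptic Connectivity of
    Segmented Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts centerline skeletons from voxel segmentations of
    single neurons using a TEASAR-style penalized shortest-path tracer over
    the distance-from-boundary field, cleans them up (hair removal, soma
    branch removal, resampling, smoothing), reads and writes SWC in plain
    text and a compact binary layout, computes per-segment and per-neuron
    morphometric features (Sholl profiles, tortuosity, fractal dimension,
    convex hull volume, surface area), scores morphological similarity with
    an NBLAST implementation written from scratch, and relates morphology to
    synaptic connectivity matrices built from synapse tables. A synthetic
    module generates voxel phantoms with exact ground-truth centerlines and
    circuits with planted community structure so the whole pipeline is
    testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
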