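#' Decompose a skeleton into unbranched segments
#'
#' Cuts a single-tree skeleton at every irreducible node (root, branching
#' node, terminal node) into maximal unbranched segments. Segment order
#' increases from the root: root-adjacent segments have order 0 and a child
#' segment's order is its parent segment's order plus one. The segments
#' partition the edge set.
#'
#' @param skel A [skeleton()] with exactly one tree (reconnect or split a
#'   forest first).
#' @return An object of class `segment_decomposition` with the row paths of
#'   each segment (proximal to distal), per-segment `order`, `is_terminal`
#'   and parent-segment index.
#' @export
decompose_skeleton <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  roots <- skel_root_rows(skel)
  if (length(roots) != 1L)
    stop("skeleton must be a single tree; reconnect components first or call per tree")
  children <- skel_children(skel)
  nch <- lengths(children)
  segs <- tree_segments(skel, roots, children)
  k <- length(segs$paths)
  distal <- vapply(segs$paths, function(p) p[length(p)], integer(1))
  prox <- vapply(segs$paths, function(p) p[1L], integer(1))
  parent_seg <- match(prox, distal)  # NA for root-adjacent segments
  structure(
    list(skel = skel, paths = segs$paths, order = segs$order,
         is_terminal = nch[distal] == 0L,
         prox_row = prox, distal_row = distal, parent_seg = parent_seg,
         root_row = roots),
    class = "segment_decomposition"
  )
}

#' @export
print.segment_decomposition <- function(x, ...) {
  cat(sprintf("<segment_decomposition> %d segments (%d terminal), max order %s\n",
              length(x$paths), sum(x$is_terminal),
              if (length(x$order)) max(x$order) else "-"))
  invisible(x)
}

# Mean pairwise branching angle at every branching node (>= 2 child
# segments). Direction toward each daughter segment's *distal* irreducible
# node, which is robust to node jitter near the branch point.
branching_node_angles <- function(decomp) {
  P <- skel_xyz(decomp$skel)
  b_nodes <- unique(decomp$prox_row[duplicated(decomp$prox_row)])
  angles <- numeric(0)
  for (b in b_nodes) {
    daughters <- which(decomp$prox_row == b)
    dirs <- lapply(daughters, function(s) {
      v <- P[decomp$distal_row[s], ] - P[b, ]
      if (vec_norm(v) == 0) return(NULL)
      unit_vec(v)
    })
    dirs <- dirs[!vapply(dirs, is.null, logical(1))]
    if (length(dirs) < 2L) {
      angles <- c(angles, NA_real_)
      next
    }
    pair_angles <- c()
    for (i in seq_len(length(dirs) - 1L))
      for (j in (i + 1L):length(dirs))
        pair_angles <- c(pair_angles,
                         acos(pmin(1, pmax(-1, sum(dirs[[i]] * dirs[[j]])))))
    angles <- c(angles, mean(pair_angles))
  }
  stats::setNames(angles, b_nodes)
}

#' Per-segment morphometric features
#'
#' One row per segment: branch `order`, path length, tortuosity (path length
#' over the Euclidean chord between the segment's irreducible endpoints;
#' `NA` when the chord is zero), minimum path distance from the segment's
#' proximal node to the root, mean node radius, the mean pairwise branching
#' angle at the segment's distal node (when it branches), and — for
#' terminal segments — the neck/head radius ratio (minimum radius in the
#' proximal arc-length half over maximum radius in the distal half), a spine
#' signature.
#'
#' @param decomp A [decompose_skeleton()] result.
#' @return A data frame with one row per segment.
#' @export
segment_features <- function(decomp) {
  stopifnot(inherits(decomp, "segment_decomposition"))
  skel <- decomp$skel
  P <- skel_xyz(skel)
  k <- length(decomp$paths)
  len <- vapply(decomp$paths, function(p) path_length_of(P, p), numeric(1))
  chord <- sqrt(rowSums((P[decomp$distal_row, , drop = FALSE] -
                           P[decomp$prox_row, , drop = FALSE])^2))
  tortuosity <- ifelse(chord > 0, len / chord, NA_real_)
  # Path distance from each segment's proximal node to the root.
  dist_to_root <- numeric(k)
  for (s in order(decomp$order)) {
    ps <- decomp$parent_seg[s]
    dist_to_root[s] <- if (is.na(ps)) 0 else dist_to_root[ps] + len[ps]
  }
  node_angles <- branching_node_angles(decomp)
  angle <- node_angles[as.character(decomp$distal_row)]
  mean_radius <- vapply(decomp$paths,
                        function(p) mean(skel$radius[p]), numeric(1))
  neck_head <- rep(NA_real_, k)
  for (s in which(decomp$is_terminal)) {
    p <- decomp$paths[[s]]
    steps <- sqrt(rowSums((P[p[-1L], , drop = FALSE] -
                             P[p[-length(p)], , drop = FALSE])^2))
    arc <- c(0, cumsum(steps))
    half <- arc[length(arc)] / 2
    neck <- min(skel$radius[p[arc <= half]])
    head <- max(skel$radius[p[arc >= half]])
    neck_head[s] <- if (head > 0) neck / head else NA_real_
  }
  data.frame(
    segment = seq_len(k),
    order = decomp$order,
    is_terminal = decomp$is_terminal,
    path_length_nm = len,
    branching_angle_rad = unname(angle),
    tortuosity = tortuosity,
    dist_to_root_nm = dist_to_root,
    mean_radius_nm = mean_radius,
    neck_head_ratio = neck_head
  )
}

#' Sholl analysis
#'
#' Counts intersections of the skeleton with concentric spheres centered on
#' the root node: an edge `(a, b)` crosses radius `r` when
#' `(|a - root| - r) * (|b - root| - r) < 0`, and a node lying exactly at
#' `r` counts once.
#'
#' @param skel A single-tree [skeleton()].
#' @param radii_nm Strictly increasing positive radii, nm.
#' @return Integer vector of crossing counts, one per radius.
#' @export
sholl <- function(skel, radii_nm) {
  stopifnot(inherits(skel, "skeleton"))
  roots <- skel_root_rows(skel)
  if (length(roots) != 1L) stop("sholl analysis needs a single-tree skeleton")
  if (any(radii_nm <= 0) || is.unsorted(radii_nm, strictly = TRUE))
    stop("`radii_nm` must be strictly increasing and positive")
  P <- skel_xyz(skel)
  d <- sqrt(rowSums(sweep(P, 2L, P[roots, ], "-")^2))
  e <- skel_edge_rows(skel)
  vapply(radii_nm, function(r) {
    crossings <- if (nrow(e) > 0L)
      sum((d[e[, 1L]] - r) * (d[e[, 2L]] - r) < 0) else 0L
    as.integer(crossings + sum(d == r))
  }, integer(1))
}

#' Box-counting fractal dimension of a point set
#'
#' Covers the points with cubic boxes at dyadic sizes from half the largest
#' extent down to 1/64 of it and returns the least-squares slope of
#' `log N(s)` against `log(1 / s)`. Undefined (`NA`) for fewer than 32
#' points or a degenerate (zero-extent) set.
#'
#' @param points Numeric matrix (n x 3) of coordinates, or a [skeleton()]
#'   whose node coordinates are used.
#' @return Estimated dimension, or `NA_real_` when undefined.
#' @export
fractal_dimension <- function(points) {
  if (inherits(points, "skeleton")) points <- skel_xyz(points)
  points <- as.matrix(points)
  if (nrow(points) < 32L) return(NA_real_)
  mins <- apply(points, 2L, min)
  extent <- max(apply(points, 2L, max) - mins)
  if (extent == 0) return(NA_real_)
  sizes <- extent / 2^(1:6)
  n_boxes <- vapply(sizes, function(s) {
    idx <- floor(sweep(points, 2L, mins, "-") / s)
    idx <- pmin(idx, floor(extent / s))  # points on the far boundary
    nrow(unique(idx))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(n_boxes) ~ log(1 / sizes)))[2L])
}

#' Convex hull volume of a point set
#'
#' Volume of the 3D convex hull in nm^3; 0 for degenerate (fewer than four
#' distinct points, or coplanar) input.
#'
#' @param points Numeric matrix (n x 3), or a [skeleton()].
#' @return Numeric scalar >= 0.
#' @export
hull_volume <- function(points) {
  if (inherits(points, "skeleton")) points <- skel_xyz(points)
  convex_hull_volume(as.matrix(points))
}

#' Skeleton surface area
#'
#' Models each parent edge as the lateral surface of a conical frustum:
#' `pi * (r1 + r2) * slant` with `slant = sqrt(len^2 + (r1 - r2)^2)`, summed
#' over all edges.
#'
#' @param skel A [skeleton()].
#' @return Surface area in nm^2.
#' @export
surface_area <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  e <- skel_edge_rows(skel)
  if (nrow(e) == 0L) return(0)
  P <- skel_xyz(skel)
  len <- sqrt(rowSums((P[e[, 1L], , drop = FALSE] -
                         P[e[, 2L], , drop = FALSE])^2))
  r1 <- skel$radius[e[, 1L]]
  r2 <- skel$radius[e[, 2L]]
  sum(pi * (r1 + r2) * sqrt(len^2 + (r1 - r2)^2))
}

#' Whole-neuron feature vector
#'
#' Aggregates the per-neuron features used for population analysis: distance
#' from the soma (root) to the arbor's center of mass (reported both as
#' `soma_to_mass_center_nm` and as the equivalent `asymmetry_nm`), total
#' path length, branching point count, median and longest segment length,
#' mean branching angle, mean tortuosity, typical radius (RMS distance of
#' nodes to the center of mass), box-counting fractal dimension, root
#' radius, convex hull volume, frustum surface area, a Sholl profile, and —
#' when a synapse table is supplied — pre- and postsynaptic site counts.
#'
#' @param skel A single-tree [skeleton()].
#' @param synapses Optional synapse table (see [synapse_table()]); requires
#'   `neuron_id`.
#' @param neuron_id Id of this neuron in `synapses`.
#' @param sholl_radii_nm Radii for the Sholl profile; defaults to 20 evenly
#'   spaced spheres spanning the arbor's radial extent.
#' @return A list of named features (`sholl_counts` is a vector, the rest
#'   scalars).
#' @export
neuron_features <- function(skel, synapses = NULL, neuron_id = NULL,
                            sholl_radii_nm = NULL) {
  decomp <- decompose_skeleton(skel)
  feats <- segment_features(decomp)
  P <- skel_xyz(skel)
  root <- skel_root_rows(skel)
  mass_center <- colMeans(P)
  asym <- vec_norm(P[root, ] - mass_center)
  centered <- sweep(P, 2L, mass_center, "-")
  typical_radius <- sqrt(mean(rowSums(centered^2)))
  radial <- sqrt(rowSums(sweep(P, 2L, P[root, ], "-")^2))
  if (is.null(sholl_radii_nm)) {
    rmax <- max(radial)
    sholl_radii_nm <- if (rmax > 0) seq(rmax / 20, rmax, length.out = 20L)
    else numeric(0)
  }
  n_branch <- sum(table(decomp$prox_row) >= 2L)
  n_pre <- n_post <- NA_integer_
  if (!is.null(synapses)) {
    if (is.null(neuron_id))
      stop("`neuron_id` is required to count synapses")
    n_pre <- sum(as.character(synapses$presyn) == as.character(neuron_id))
    n_post <- sum(as.character(synapses$postsyn) == as.character(neuron_id))
  }
  list(
    soma_to_mass_center_nm = asym,
    total_path_length_nm = total_path_length(skel),
    n_branching_points = n_branch,
    median_segment_length_nm = stats::median(feats$path_length_nm),
    sholl_counts = if (length(sholl_radii_nm)) sholl(skel, sholl_radii_nm)
    else integer(0),
    sholl_radii_nm = sholl_radii_nm,
    mean_branching_rad = if (all(is.na(feats$branching_angle_rad)))
      NA_real_ else mean(feats$branching_angle_rad, na.rm = TRUE),
    mean_tortuosity = if (all(is.na(feats$tortuosity))) NA_real_
    else mean(feats$tortuosity, na.rm = TRUE),
    asymmetry_nm = asym,
    typical_radius_nm = typical_radius,
    fractal_dimension = fractal_dimension(P),
    root_radius_nm = skel$radius[root],
    longest_segment_nm = max(feats$path_length_nm),
    hull_volume_nm3 = hull_volume(P),
    surface_area_nm2 = surface_area(skel),
    n_postsynapses = n_post,
    n_presynapses = n_pre
  )
}

#' Feature table for a set of neurons
#'
#' Scalar features from [neuron_features()], one row per neuron, suitable
#' for CSV export.
#'
#' @param skels Named list of single-tree [skeleton()]s.
#' @param synapses Optional [synapse_table()]; neuron ids are taken from
#'   `names(skels)`.
#' @return A data frame with a `neuron` column followed by scalar features.
#' @export
neuron_feature_table <- function(skels, synapses = NULL) {
  ids <- names(skels)
  if (is.null(ids)) ids <- as.character(seq_along(skels))
  rows <- lapply(seq_along(skels), function(i) {
    f <- neuron_features(skels[[i]], synapses = synapses,
                         neuron_id = ids[i])
    f$sholl_counts <- NULL
    f$sholl_radii_nm <- NULL
    data.frame(neuron = ids[i], f)
  })
  do.call(rbind, rows)
}
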