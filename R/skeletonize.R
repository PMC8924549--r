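#' Parameters for TEASAR-style skeleton tracing
#'
#' The tracer prefers paths through the middle of the object by adding a
#' center-hugging penalty to every step: the cost of stepping onto point `v`
#' is the physical step length plus
#' `penalty_scale_nm * (1 - dbf(v) / dbf_max)^penalty_exponent`,
#' so steps onto near-boundary voxels (small DBF) are expensive and steps
#' along the medial axis are almost free.
#'
#' @param penalty_scale_nm Magnitude of the boundary penalty, nm.
#' @param penalty_exponent Sharpness of the penalty (>= 1); large values
#'   penalize only voxels very close to the boundary.
#' @param invalidation_scale Multiple of a path node's DBF within which
#'   surrounding points are marked visited after tracing a path.
#' @param invalidation_min_nm Floor of the invalidation radius, nm. `NULL`
#'   (default) resolves to twice the smallest voxel spacing at trace time.
#' @param reconnect_threshold_nm Maximum gap bridged when reconnecting
#'   disconnected skeleton fragments.
#' @param rng_seed Kept for provenance; the trace loop itself is
#'   deterministic and consumes no random numbers.
#' @return An object of class `skeletonize_params`.
#' @export
skeletonize_params <- function(penalty_scale_nm = 5000,
                               penalty_exponent = 16,
                               invalidation_scale = 3.0,
                               invalidation_min_nm = NULL,
                               reconnect_threshold_nm = 5000,
                               rng_seed = 1L) {
  vals <- c(penalty_scale_nm, penalty_exponent, invalidation_scale,
            reconnect_threshold_nm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all parameters must be positive")
  if (penalty_exponent < 1) stop("`penalty_exponent` must be >= 1")
  if (!is.null(invalidation_min_nm) && invalidation_min_nm <= 0)
    stop("`invalidation_min_nm` must be positive")
  structure(
    list(penalty_scale_nm = penalty_scale_nm,
         penalty_exponent = penalty_exponent,
         invalidation_scale = invalidation_scale,
         invalidation_min_nm = invalidation_min_nm,
         reconnect_threshold_nm = reconnect_threshold_nm,
         rng_seed = as.integer(rng_seed)),
    class = "skeletonize_params"
  )
}

#' Build the 26-neighborhood voxel graph of a point cloud
#'
#' Nodes are the cloud's points; two points are adjacent iff their voxel
#' indices differ by at most 1 on every axis (and are not identical). The
#' adjacency relation is undirected, but edge costs are stored as directed
#' arc pairs because the center-hugging penalty depends on the arc target:
#' `weight(u -> v) = ||pos(u) - pos(v)||_nm +
#'   penalty_scale_nm * (1 - dbf(v) / dbf_max)^penalty_exponent`.
#'
#' @param cloud A [point_cloud()] with `dbf_nm` set.
#' @param params A [skeletonize_params()].
#' @return An object of class `voxel_graph`: node count `n` and arc vectors
#'   `from`, `to`, `weight`.
#' @export
build_voxel_graph <- function(cloud, params = skeletonize_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L) stop_empty_object()
  if (is.null(cloud$dbf_nm)) stop("cloud must have dbf set; see compute_dbf()")
  pts <- cloud$points_vox
  n <- nrow(pts)
  rng <- apply(pts, 2L, range)
  lo <- rng[1L, ]
  Dx <- rng[2L, 1L] - lo[1L] + 1
  Dy <- rng[2L, 2L] - lo[2L] + 1
  key <- (pts[, 1L] - lo[1L]) +
    (pts[, 2L] - lo[2L]) * Dx +
    (pts[, 3L] - lo[3L]) * Dx * Dy
  dbf_max <- max(cloud$dbf_nm)
  penalty <- params$penalty_scale_nm *
    (1 - cloud$dbf_nm / dbf_max)^params$penalty_exponent
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  from <- to <- integer(0)
  weight <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ni <- pts[, 1L] + o[1L]
    nj <- pts[, 2L] + o[2L]
    nk <- pts[, 3L] + o[3L]
    valid <- ni >= lo[1L] & ni <= rng[2L, 1L] &
      nj >= lo[2L] & nj <= rng[2L, 2L] &
      nk >= lo[3L] & nk <= rng[2L, 3L]
    nb_key <- (ni - lo[1L]) + (nj - lo[2L]) * Dx + (nk - lo[3L]) * Dx * Dy
    idx <- rep(NA_integer_, n)
    idx[valid] <- match(nb_key[valid], key)
    src <- which(!is.na(idx))
    if (length(src) == 0L) next
    dst <- idx[src]
    step_len <- sqrt(sum((o * cloud$spacing_nm)^2))
    from <- c(from, src)
    to <- c(to, dst)
    weight <- c(weight, step_len + penalty[dst])
  }
  structure(list(n = n, from = from, to = to, weight = weight),
            class = "voxel_graph")
}

#' @export
print.voxel_graph <- function(x, ...) {
  cat(sprintf("<voxel_graph> %d nodes, %d arcs\n", x$n, length(x$from)))
  invisible(x)
}

graph_as_igraph <- function(graph) {
  ig <- igraph::make_empty_graph(graph$n, directed = TRUE)
  if (length(graph$from) > 0L) {
    ig <- igraph::add_edges(ig, rbind(graph$from, graph$to))
    igraph::E(ig)$weight <- graph$weight
  }
  ig
}

#' Find the seed point of a cloud
#'
#' The point with the largest distance from the boundary; ties are broken by
#' the lowest lexicographic voxel index.
#'
#' @param cloud A [point_cloud()] with `dbf_nm` set.
#' @return Integer index into the cloud's points.
#' @export
find_seed <- function(cloud) {
  if (n_points(cloud) == 0L) stop_empty_object()
  if (is.null(cloud$dbf_nm)) stop("cloud must have dbf set")
  m <- max(cloud$dbf_nm)
  cand <- which(cloud$dbf_nm == m)
  if (length(cand) == 1L) return(cand)
  p <- cloud$points_vox[cand, , drop = FALSE]
  cand[order(p[, 1L], p[, 2L], p[, 3L])][1L]
}

#' Single-source shortest paths on a voxel graph
#'
#' Exact Dijkstra distances and the predecessor tree from one source node.
#' Unreachable nodes get distance `Inf` and predecessor `NA`.
#'
#' @param graph A [build_voxel_graph()] result.
#' @param source Node index in `1:graph$n`.
#' @return List with numeric `dist` and integer `pred` (both length
#'   `graph$n`; the source has predecessor `NA`).
#' @export
graph_shortest_paths <- function(graph, source) {
  stopifnot(inherits(graph, "voxel_graph"))
  if (length(source) != 1L || is.na(source) || source < 1L || source > graph$n)
    skel_error("skelemorph_index_error", "source node out of range")
  dijkstra_tree(graph_as_igraph(graph), source)
}

dijkstra_tree <- function(ig, source) {
  w <- igraph::E(ig)$weight
  dist <- suppressWarnings(as.vector(
    igraph::distances(ig, v = source, mode = "out", weights = w,
                      algorithm = "dijkstra")))
  pred <- suppressWarnings(
    igraph::shortest_paths(ig, from = source, to = igraph::V(ig),
                           mode = "out", weights = w,
                           predecessors = TRUE, output = "vpath")$predecessors)
  pred <- as.integer(pred)
  pred[source] <- NA_integer_
  pred[!is.finite(dist)] <- NA_integer_
  list(dist = dist, pred = pred)
}

#' Trace the centerline skeleton of a point cloud
#'
#' TEASAR-style tracing. Per connected component of the voxel graph: seed at
#' the maximum-DBF point; repeatedly run Dijkstra from the current seed,
#' take the farthest (by penalized graph distance) unvisited point as the
#' destination, walk the predecessor chain back — stopping at the first
#' already-skeletonized node, which becomes the attachment point — and mark
#' every point within `max(invalidation_scale * dbf(n), invalidation_min_nm)`
#' of a new path node as visited. The next seed is the unvisited point
#' closest (Euclidean) to the visited set. Iterate until every point is
#' visited. Node radii are the DBF at the node's voxel; each component
#' yields one tree rooted at its largest-radius node.
#'
#' The loop consumes no random numbers: identical inputs give identical
#' skeletons.
#'
#' @param cloud A [point_cloud()] with `dbf_nm` set.
#' @param params A [skeletonize_params()].
#' @return A [skeleton()] (one tree per graph component).
#' @export
trace_skeleton <- function(cloud, params = skeletonize_params()) {
  if (n_points(cloud) == 0L) stop_empty_object()
  if (is.null(cloud$dbf_nm)) stop("cloud must have dbf set; see compute_dbf()")
  n <- n_points(cloud)
  pos <- point_positions_nm(cloud)
  inval_min <- params$invalidation_min_nm
  if (is.null(inval_min)) inval_min <- 2 * min(cloud$spacing_nm)

  graph <- build_voxel_graph(cloud, params)
  ig <- graph_as_igraph(graph)
  comp <- igraph::components(ig, mode = "weak")$membership

  visited <- rep(FALSE, n)
  is_skel <- rep(FALSE, n)
  edges <- matrix(integer(0), 0L, 2L)

  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    dbf_c <- cloud$dbf_nm[idx]
    seed <- idx[which.max(dbf_c)]  # points are lex-sorted: first max wins
    # One penalized shortest-path tree per component, rooted at the seed;
    # every central path is a branch of this tree, so later paths always
    # meet the existing skeleton at a single funnel point.
    sp <- dijkstra_tree(ig, seed)
    repeat {
      cand <- idx[!visited[idx]]
      dist_cand <- sp$dist[cand]
      dist_cand[!is.finite(dist_cand)] <- -Inf
      dest <- cand[which.max(dist_cand)]
      # Walk predecessors dest -> seed, stop at the skeleton if we hit it.
      path <- integer(0)
      attach_node <- NA_integer_
      v <- dest
      while (!is.na(v)) {
        if (is_skel[v]) {
          attach_node <- v
          break
        }
        path <- c(path, v)
        v <- sp$pred[v]
      }
      if (length(path) > 0L) {
        if (length(path) > 1L)
          edges <- rbind(edges, cbind(path[-length(path)], path[-1L]))
        if (!is.na(attach_node))
          edges <- rbind(edges, c(path[length(path)], attach_node))
        is_skel[path] <- TRUE
      }
      # Invalidate points near the new path nodes.
      radius <- pmax(params$invalidation_scale * cloud$dbf_nm[path], inval_min)
      un <- idx[!visited[idx]]
      if (length(un) > 0L && length(path) > 0L) {
        d2 <- cross_dist2(pos[un, , drop = FALSE], pos[path, , drop = FALSE])
        hit <- rowSums(d2 <= matrix(radius^2, nrow = length(un),
                                    ncol = length(path), byrow = TRUE)) > 0L
        visited[un[hit]] <- TRUE
      }
      visited[path] <- TRUE
      visited[dest] <- TRUE
      if (all(visited[idx])) break
    }
  }

  keep <- which(is_skel)
  remap <- match(seq_len(n), keep)
  kept_edges <- cbind(remap[edges[, 1L]], remap[edges[, 2L]])
  kept_edges <- kept_edges[stats::complete.cases(kept_edges), , drop = FALSE]
  skeleton_from_edges(pos[keep, , drop = FALSE], cloud$dbf_nm[keep],
                      kept_edges)
}

#' Reconnect disconnected skeleton fragments
#'
#' While at least two trees remain and the globally nearest pair of
#' terminal-or-root nodes from different trees is within `threshold_nm`,
#' bridge that pair with an edge (greedy, ascending gap). The tree whose
#' root has the smaller radius is absorbed: it is re-rooted at its end of
#' the bridge and hung under the other tree.
#'
#' @param skel A [skeleton()] forest.
#' @param threshold_nm Maximum gap to bridge, nm (use `Inf` to force a
#'   single tree).
#' @return A [skeleton()] with at most as many trees as the input.
#' @export
reconnect_components <- function(skel, threshold_nm = 5000) {
  stopifnot(inherits(skel, "skeleton"))
  repeat {
    memb <- skel_tree_membership(skel)
    if (length(unique(memb)) < 2L) return(skel)
    children <- skel_children(skel)
    cand <- sort(unique(c(skel_terminal_rows(skel, children),
                          skel_root_rows(skel))))
    P <- skel_xyz(skel)[cand, , drop = FALSE]
    d2 <- cross_dist2(P, P)
    same <- outer(memb[cand], memb[cand], "==")
    d2[same] <- Inf
    best <- which.min(d2)
    gap <- sqrt(d2[best])
    if (!is.finite(gap) || gap > threshold_nm) return(skel)
    ij <- arrayInd(best, dim(d2))
    a <- cand[ij[1L]]
    b <- cand[ij[2L]]
    # Absorb the tree with the smaller-radius root.
    root_radius <- function(row) {
      r <- skel_root_rows(skel)
      skel$radius[r[memb[r] == memb[row]]]
    }
    if (root_radius(a) < root_radius(b)) { tmp <- a; a <- b; b <- tmp }
    skel <- reroot_at(skel, skel$id[b])
    skel$parent[match(skel$id[b], skel$id)] <- skel$id[a]
    skel <- skeleton(skel, validate = FALSE)
  }
}

#' Skeletonize one object end to end
#'
#' Convenience wrapper: bit-pack the object's mask, compute the DBF, trace
#' the skeleton, reconnect fragments within the threshold, and run the
#' cleanup pipeline.
#'
#' @param chunk A [seg_chunk()].
#' @param object_id Positive object ID present in the chunk.
#' @param params A [skeletonize_params()].
#' @param post A [postprocess_params()], or `NULL` to skip cleanup.
#' @return A [skeleton()].
#' @export
skeletonize_object <- function(chunk, object_id,
                               params = skeletonize_params(),
                               post = postprocess_params()) {
  cloud <- compute_dbf(pack_mask(chunk, object_id))
  skel <- trace_skeleton(cloud, params)
  skel <- reconnect_components(skel, params$reconnect_threshold_nm)
  if (!is.null(post)) {
    if (is.null(post$redundant_eps_nm))
      post$redundant_eps_nm <- min(chunk$spacing_nm)
    skel <- postprocess(skel, post)
  }
  skel
}
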