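# Skeleton cleanup: redundant-node removal, hair removal, soma-branch
# removal, resampling, empty-branch removal, smoothing.

# Maximal unbranched row paths of one tree, proximal -> distal, each
# starting and ending at an irreducible node (root, branching or terminal).
# Returns list(paths = list(integer vectors), order = integer per path).
tree_segments <- function(skel, root_row, children) {
  nch <- lengths(children)
  paths <- list()
  order_of <- integer(0)
  stack_node <- root_row
  stack_order <- 0L
  while (length(stack_node) > 0L) {
    a <- stack_node[1L]
    o <- stack_order[1L]
    stack_node <- stack_node[-1L]
    stack_order <- stack_order[-1L]
    for (child in children[[a]]) {
      path <- c(a, child)
      v <- child
      while (nch[v] == 1L) {
        v <- children[[v]][1L]
        path <- c(path, v)
      }
      paths[[length(paths) + 1L]] <- path
      order_of <- c(order_of, o)
      stack_node <- c(stack_node, v)
      stack_order <- c(stack_order, o + 1L)
    }
  }
  list(paths = paths, order = order_of)
}

# Apply fn(path_rows) over every segment of every tree.
for_each_segment <- function(skel, fn) {
  children <- skel_children(skel)
  for (root in skel_root_rows(skel)) {
    segs <- tree_segments(skel, root, children)
    for (path in segs$paths) fn(path)
  }
}

path_length_of <- function(P, path) {
  if (length(path) < 2L) return(0)
  sum(sqrt(rowSums((P[path[-1L], , drop = FALSE] -
                      P[path[-length(path)], , drop = FALSE])^2)))
}

#' Parameters for skeleton cleanup
#'
#' @param hair_ratio A terminal segment hanging off a branching node is
#'   "hair" (a tracing artifact along the object surface) when its path
#'   length is below `hair_ratio` times the attachment node's diameter.
#' @param resample_spacing_nm Target node spacing along each segment, nm.
#' @param smooth_window Odd window (>= 3) of the centered moving average
#'   applied to node coordinates along segments.
#' @param redundant_eps_nm Consecutive nodes closer than this are merged.
#'   `NULL` merges only coincident nodes; [skeletonize_object()] resolves
#'   `NULL` to the smallest voxel spacing.
#' @return An object of class `postprocess_params`.
#' @export
postprocess_params <- function(hair_ratio = 1.5,
                               resample_spacing_nm = 500,
                               smooth_window = 3L,
                               redundant_eps_nm = NULL) {
  if (hair_ratio <= 0 || resample_spacing_nm <= 0)
    stop("all parameters must be positive")
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 3L || smooth_window %% 2L == 0L)
    stop("`smooth_window` must be an odd integer >= 3")
  if (!is.null(redundant_eps_nm) && redundant_eps_nm <= 0)
    stop("`redundant_eps_nm` must be positive")
  structure(
    list(hair_ratio = hair_ratio,
         resample_spacing_nm = resample_spacing_nm,
         smooth_window = smooth_window,
         redundant_eps_nm = redundant_eps_nm),
    class = "postprocess_params"
  )
}

#' Merge redundant (near-coincident) consecutive nodes
#'
#' Walks every unbranched segment and greedily merges consecutive nodes
#' closer than `eps_nm`, keeping the larger-radius node of a merged pair.
#' Irreducible nodes (segment endpoints) are never merged away: an interior
#' node within `eps_nm` of one simply disappears.
#'
#' @param skel A [skeleton()].
#' @param eps_nm Merge distance, nm.
#' @return A [skeleton()].
#' @export
remove_redundant_nodes <- function(skel, eps_nm) {
  stopifnot(inherits(skel, "skeleton"), eps_nm > 0)
  P <- skel_xyz(skel)
  drop <- rep(FALSE, nrow(skel))
  parent_new <- skel$parent
  children <- skel_children(skel)
  for (root in skel_root_rows(skel)) {
    segs <- tree_segments(skel, root, children)
    for (path in segs$paths) {
      m <- length(path)
      if (m <= 2L) next
      kept <- path[1L]
      for (i in 2:(m - 1L)) {
        v <- path[i]
        last <- kept[length(kept)]
        gap <- sqrt(sum((P[last, ] - P[v, ])^2))
        if (gap < eps_nm) {
          if (last == path[1L]) {
            drop[v] <- TRUE           # never merge away the proximal endpoint
          } else if (skel$radius[v] > skel$radius[last]) {
            drop[last] <- TRUE        # keep the larger-radius node
            kept[length(kept)] <- v
          } else {
            drop[v] <- TRUE
          }
        } else {
          kept <- c(kept, v)
        }
      }
      last <- kept[length(kept)]
      if (last != path[1L] &&
          sqrt(sum((P[last, ] - P[path[m], ])^2)) < eps_nm) {
        drop[last] <- TRUE
        kept <- kept[-length(kept)]
      }
      chain <- c(kept, path[m])
      for (i in seq_len(length(chain) - 1L))
        parent_new[chain[i + 1L]] <- skel$id[chain[i]]
    }
  }
  skel$parent <- parent_new
  skeleton(skel[!drop, , drop = FALSE], validate = FALSE)
}

#' Remove hair: short terminal segments off branching nodes
#'
#' Deletes every terminal segment attached at a branching node whose path
#' length is less than `hair_ratio * (2 * radius of the attachment node)`,
#' iterating until no segment qualifies. Segments attached at the root are
#' exempt.
#'
#' @param skel A [skeleton()].
#' @param hair_ratio Dimensionless threshold on path length over attachment
#'   diameter.
#' @return A [skeleton()].
#' @export
remove_hair <- function(skel, hair_ratio = 1.5) {
  stopifnot(inherits(skel, "skeleton"), hair_ratio > 0)
  repeat {
    children <- skel_children(skel)
    nch <- lengths(children)
    roots <- skel_root_rows(skel)
    P <- skel_xyz(skel)
    drop <- rep(FALSE, nrow(skel))
    for (root in roots) {
      segs <- tree_segments(skel, root, children)
      for (path in segs$paths) {
        prox <- path[1L]
        distal <- path[length(path)]
        if (nch[distal] != 0L) next       # not terminal
        if (prox %in% roots) next         # root-containing segment exempt
        if (nch[prox] < 2L) next          # attachment must be a branching node
        len <- path_length_of(P, path)
        if (len < hair_ratio * 2 * skel$radius[prox])
          drop[path[-1L]] <- TRUE
      }
    }
    if (!any(drop)) return(skel)
    skel <- skel_drop_rows(skel, which(drop))
  }
}

#' Remove branches inside the cell body
#'
#' The root node is the soma proxy; any maximal subtree lying entirely
#' within the sphere centered on the root with the root's radius is deleted.
#' Branches that exit the sphere are kept. A zero-radius root changes
#' nothing.
#'
#' @param skel A [skeleton()].
#' @return A [skeleton()].
#' @export
remove_soma_branches <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  memb <- skel_tree_membership(skel)
  children <- skel_children(skel)
  pidx <- skel_parent_rows(skel)
  P <- skel_xyz(skel)
  drop <- rep(FALSE, nrow(skel))
  for (root in skel_root_rows(skel)) {
    rr <- skel$radius[root]
    if (rr <= 0) next
    rows <- which(memb == memb[root])
    inside <- rep(FALSE, nrow(skel))
    inside[rows] <- sqrt(rowSums(sweep(P[rows, , drop = FALSE], 2L,
                                       P[root, ], "-")^2)) <= rr
    # Postorder: subtree fully inside iff node and all child subtrees inside.
    ord <- rows[order(node_depths(pidx, rows), decreasing = TRUE)]
    sub_inside <- rep(FALSE, nrow(skel))
    for (v in ord)
      sub_inside[v] <- inside[v] && all(sub_inside[children[[v]]])
    # Maximal fully-inside subtrees (excluding the root itself).
    for (v in rows) {
      if (v == root || !sub_inside[v]) next
      p <- pidx[v]
      if (p == root || !sub_inside[p])
        drop[subtree_rows(skel, v, children)] <- TRUE
    }
  }
  skel_drop_rows(skel, which(drop))
}

node_depths <- function(pidx, rows) {
  depth <- integer(length(pidx))
  for (v in rows) {
    d <- 0L
    u <- v
    while (!is.na(pidx[u])) {
      d <- d + 1L
      u <- pidx[u]
    }
    depth[v] <- d
  }
  depth[rows]
}

lin_interp <- function(s, y, t) {
  stats::approx(s, y, xout = t, rule = 2L, ties = "ordered")$y
}

#' Resample segments to uniform node spacing
#'
#' Each unbranched segment is re-parameterized by arc length and sampled at
#' (close to) `spacing_nm` intervals; irreducible node positions are
#' preserved exactly and interior radii are linearly interpolated. A segment
#' of length `L` gets `max(1, round(L / spacing_nm))` intervals, so a short
#' segment reduces to its two endpoints.
#'
#' @param skel A [skeleton()].
#' @param spacing_nm Target spacing, nm.
#' @return A [skeleton()].
#' @export
resample_skeleton <- function(skel, spacing_nm) {
  stopifnot(inherits(skel, "skeleton"), spacing_nm > 0)
  children <- skel_children(skel)
  nch <- lengths(children)
  roots <- skel_root_rows(skel)
  irreducible <- rep(FALSE, nrow(skel))
  irreducible[roots] <- TRUE
  irreducible[nch != 1L] <- TRUE
  P <- skel_xyz(skel)
  out <- skel[irreducible, , drop = FALSE]
  next_id <- max(skel$id) + 1L
  extra <- list()
  for (root in roots) {
    segs <- tree_segments(skel, root, children)
    for (path in segs$paths) {
      steps <- sqrt(rowSums((P[path[-1L], , drop = FALSE] -
                               P[path[-length(path)], , drop = FALSE])^2))
      s <- c(0, cumsum(steps))
      L <- s[length(s)]
      n_int <- max(1L, round(L / spacing_nm))
      prox_id <- skel$id[path[1L]]
      distal_id <- skel$id[path[length(path)]]
      if (n_int > 1L && L > 0) {
        t <- L * seq_len(n_int - 1L) / n_int
        ids <- next_id + seq_len(n_int - 1L) - 1L
        next_id <- next_id + n_int - 1L
        extra[[length(extra) + 1L]] <- data.frame(
          id = ids, type = 0L,
          x = lin_interp(s, P[path, 1L], t),
          y = lin_interp(s, P[path, 2L], t),
          z = lin_interp(s, P[path, 3L], t),
          radius = lin_interp(s, skel$radius[path], t),
          parent = c(prox_id, ids[-length(ids)])
        )
        out$parent[out$id == distal_id] <- ids[length(ids)]
      } else {
        out$parent[out$id == distal_id] <- prox_id
      }
    }
  }
  skeleton(rbind(out, do.call(rbind, extra)), validate = FALSE)
}

#' Remove empty branches
#'
#' Deletes terminal segments of zero path length (a terminal chain
#' coincident with its attachment node). Idempotent.
#'
#' @param skel A [skeleton()].
#' @return A [skeleton()].
#' @export
remove_empty_branches <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  children <- skel_children(skel)
  nch <- lengths(children)
  P <- skel_xyz(skel)
  drop <- rep(FALSE, nrow(skel))
  for (root in skel_root_rows(skel)) {
    segs <- tree_segments(skel, root, children)
    for (path in segs$paths) {
      if (nch[path[length(path)]] != 0L) next
      if (path_length_of(P, path) == 0)
        drop[path[-1L]] <- TRUE
    }
  }
  skel_drop_rows(skel, which(drop))
}

#' Smooth node coordinates along segments
#'
#' Centered moving average of the coordinates along each unbranched segment;
#' irreducible nodes (segment endpoints) stay fixed, and near an endpoint
#' the window shrinks symmetrically so the average stays centered.
#'
#' @param skel A [skeleton()].
#' @param window Odd window size >= 3.
#' @return A [skeleton()].
#' @export
smooth_skeleton <- function(skel, window = 3L) {
  stopifnot(inherits(skel, "skeleton"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("`window` must be odd >= 3")
  h <- (window - 1L) %/% 2L
  children <- skel_children(skel)
  P <- skel_xyz(skel)
  newP <- P
  for (root in skel_root_rows(skel)) {
    segs <- tree_segments(skel, root, children)
    for (path in segs$paths) {
      m <- length(path)
      if (m < 3L) next
      for (i in 2:(m - 1L)) {
        hh <- min(h, i - 1L, m - i)
        win <- path[(i - hh):(i + hh)]
        newP[path[i], ] <- colMeans(P[win, , drop = FALSE])
      }
    }
  }
  skel$x <- newP[, 1L]
  skel$y <- newP[, 2L]
  skel$z <- newP[, 3L]
  skeleton(skel, validate = FALSE)
}

#' Full cleanup pipeline
#'
#' Applies, in order: redundant-node removal, hair removal, soma-branch
#' removal, resampling, empty-branch removal, smoothing.
#'
#' @param skel A [skeleton()].
#' @param params A [postprocess_params()].
#' @return A [skeleton()].
#' @export
postprocess <- function(skel, params = postprocess_params()) {
  stopifnot(inherits(skel, "skeleton"), inherits(params, "postprocess_params"))
  eps <- params$redundant_eps_nm
  if (is.null(eps)) eps <- 1e-9
  skel <- remove_redundant_nodes(skel, eps)
  skel <- remove_hair(skel, params$hair_ratio)
  skel <- remove_soma_branches(skel)
  skel <- resample_skeleton(skel, params$resample_spacing_nm)
  skel <- remove_empty_branches(skel)
  smooth_skeleton(skel, params$smooth_window)
}
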