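#' Skeleton: a rooted tree or forest of centerline nodes
#'
#' SWC-compatible container: a data frame with one row per node and columns
#' `id` (unique integer), `type` (SWC structure class; 1 = soma/root,
#' 0 = undefined), `x`, `y`, `z` (nm), `radius` (nm, >= 0) and `parent`
#' (id of the parent node, `-1` for roots). Parent references must resolve
#' and the parent relation must be acyclic, so a skeleton is always a forest.
#'
#' @param nodes Data frame with the seven SWC columns.
#' @param validate Check invariants (unique ids, resolving parents, no
#'   cycles, non-negative radii). Internal callers that construct skeletons
#'   by valid means may skip this.
#' @return An object of class `skeleton` (also a `data.frame`).
#' @examples
#' skel <- skeleton(data.frame(
#'   id = 1:3, type = c(1L, 0L, 0L),
#'   x = c(0, 10, 20), y = 0, z = 0, radius = c(5, 1, 1),
#'   parent = c(-1L, 1L, 2L)))
#' @export
skeleton <- function(nodes, validate = TRUE) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes)))
    stop("`nodes` must have columns ", paste(required, collapse = ", "))
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  rownames(nodes) <- NULL
  if (validate) validate_skeleton(nodes)
  structure(nodes, class = c("skeleton", "data.frame"))
}

validate_skeleton <- function(nodes) {
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (any(nodes$radius < 0)) stop("radii must be >= 0")
  nonroot <- nodes$parent != -1L
  if (any(is.na(match(nodes$parent[nonroot], nodes$id))))
    stop("dangling parent reference")
  if (any(nodes$parent == nodes$id)) stop("node cannot be its own parent")
  # Cycle check: every node must reach a root.
  pidx <- match(nodes$parent, nodes$id)
  n <- nrow(nodes)
  state <- integer(n)  # 0 unseen, 1 on current walk, 2 proven
  for (s in seq_len(n)) {
    walk <- integer(0)
    v <- s
    while (!is.na(v) && state[v] == 0L) {
      state[v] <- 1L
      walk <- c(walk, v)
      v <- pidx[v]
    }
    if (!is.na(v) && state[v] == 1L) stop("parent relation contains a cycle")
    state[walk] <- 2L
  }
  invisible(nodes)
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d nodes, %d tree(s), total path length %.1f nm\n",
              nrow(x), length(skel_root_rows(x)), total_path_length(x)))
  invisible(x)
}

#' Number of nodes in a skeleton
#' @param skel A [skeleton()].
#' @return Integer node count.
#' @export
n_nodes <- function(skel) nrow(skel)

# Row indices of roots.
skel_root_rows <- function(skel) which(skel$parent == -1L)

# Row index of each node's parent (NA for roots).
skel_parent_rows <- function(skel) {
  pidx <- match(skel$parent, skel$id)
  pidx[skel$parent == -1L] <- NA_integer_
  pidx
}

# children[[row]] = integer vector of child row indices.
skel_children <- function(skel) {
  pidx <- skel_parent_rows(skel)
  ch <- vector("list", nrow(skel))
  ok <- which(!is.na(pidx))
  for (r in ok) ch[[pidx[r]]] <- c(ch[[pidx[r]]], r)
  ch
}

skel_xyz <- function(skel) as.matrix(skel[, c("x", "y", "z")])

# child/parent row pairs, one per edge.
skel_edge_rows <- function(skel) {
  pidx <- skel_parent_rows(skel)
  ch <- which(!is.na(pidx))
  cbind(child = ch, parent = pidx[ch])
}

skel_edge_lengths <- function(skel) {
  e <- skel_edge_rows(skel)
  if (nrow(e) == 0L) return(numeric(0))
  P <- skel_xyz(skel)
  sqrt(rowSums((P[e[, 1L], , drop = FALSE] - P[e[, 2L], , drop = FALSE])^2))
}

#' Total path length of a skeleton
#'
#' Sum of all parent-edge lengths over the forest, in nm.
#'
#' @param skel A [skeleton()].
#' @return Numeric scalar (0 for a skeleton without edges).
#' @export
total_path_length <- function(skel) sum(skel_edge_lengths(skel))

# Tree membership: integer label per row, one label per root.
skel_tree_membership <- function(skel) {
  pidx <- skel_parent_rows(skel)
  n <- nrow(skel)
  memb <- integer(n)
  roots <- skel_root_rows(skel)
  memb[roots] <- seq_along(roots)
  for (s in seq_len(n)) {
    if (memb[s] != 0L) next
    walk <- integer(0)
    v <- s
    while (memb[v] == 0L) {
      walk <- c(walk, v)
      v <- pidx[v]
    }
    memb[walk] <- memb[v]
  }
  memb
}

# Row indices of all nodes in the subtree rooted at `row` (inclusive).
subtree_rows <- function(skel, row, children = skel_children(skel)) {
  out <- integer(0)
  stack <- row
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, children[[v]])
  }
  out
}

# Terminal rows: nodes without children (roots with no children count too).
skel_terminal_rows <- function(skel, children = skel_children(skel)) {
  which(lengths(children) == 0L)
}

# Drop rows (a union of whole subtrees) and revalidate lazily.
skel_drop_rows <- function(skel, rows) {
  if (length(rows) == 0L) return(skel)
  kept <- skel[-rows, , drop = FALSE]
  if (any(!(kept$parent %in% c(-1L, kept$id))))
    stop("internal error: dropped rows were not whole subtrees")
  skeleton(kept, validate = FALSE)
}

# Re-root the tree containing node `new_root_id` at that node by reversing
# the parent pointers along the path to the old root.
reroot_at <- function(skel, new_root_id) {
  row <- match(new_root_id, skel$id)
  if (is.na(row)) stop("unknown node id")
  pidx <- skel_parent_rows(skel)
  chain <- integer(0)
  v <- row
  while (!is.na(v)) {
    chain <- c(chain, v)
    v <- pidx[v]
  }
  if (length(chain) > 1L) {
    for (i in seq_len(length(chain) - 1L))
      skel$parent[chain[i + 1L]] <- skel$id[chain[i]]
  }
  skel$parent[row] <- -1L
  skeleton(skel, validate = FALSE)
}

# Build an oriented skeleton from node attributes and an undirected edge
# list (row index pairs). Each connected component is rooted at its
# largest-radius node (ties: first), a soma proxy.
skeleton_from_edges <- function(pos_nm, radius_nm, edges) {
  n <- nrow(pos_nm)
  parent <- rep(-1L, n)
  type <- rep(0L, n)
  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- rep(FALSE, n)
  for (start_order in order(-radius_nm, seq_len(n))) {
    if (seen[start_order]) next
    root <- start_order
    type[root] <- 1L
    seen[root] <- TRUE
    queue <- root
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
  }
  parent_id <- ifelse(parent == -1L, -1L, parent)
  skeleton(data.frame(
    id = seq_len(n), type = type,
    x = pos_nm[, 1L], y = pos_nm[, 2L], z = pos_nm[, 3L],
    radius = radius_nm, parent = parent_id
  ), validate = FALSE)
}
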