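# Independent oracles and small generators used across the suite. These are
# deliberately naive (brute force / direct simulation) and share no code
# with the implementation they check.

# Exhaustive nearest-background search: anisotropic distance from every
# foreground voxel center to the nearest background voxel center, with the
# 1-voxel padded bounding box counting as background. Rows ordered
# lexicographically by (i, j, k) to match extract_point_cloud().
brute_dbf <- function(arr, spacing) {
  dims <- dim(arr)
  grid <- as.matrix(expand.grid(i = 0:(dims[1] + 1), j = 0:(dims[2] + 1),
                                k = 0:(dims[3] + 1))) - 1L
  fg <- which(arr, arr.ind = TRUE) - 1L
  fg <- fg[order(fg[, 1], fg[, 2], fg[, 3]), , drop = FALSE]
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  bg <- grid[!(key(grid) %in% key(fg)), , drop = FALSE]
  fgc <- sweep(fg + 0.5, 2, spacing, "*")
  bgc <- t(sweep(bg + 0.5, 2, spacing, "*"))
  apply(fgc, 1, function(p) sqrt(min(colSums((bgc - p)^2))))
}

# O(n) relaxation passes: exact single-source shortest paths on an arc list.
bellman_ford <- function(n, from, to, w, src) {
  dist <- rep(Inf, n)
  dist[src] <- 0
  for (pass in seq_len(n)) {
    cand <- dist[from] + w
    nd <- dist
    upd <- tapply(cand, to, min)
    targets <- as.integer(names(upd))
    nd[targets] <- pmin(nd[targets], upd)
    if (identical(nd, dist)) break
    dist <- nd
  }
  dist
}

# O(n^2) 26-neighborhood scan over voxel index rows.
brute_adjacency <- function(pts) {
  n <- nrow(pts)
  out <- matrix(integer(0), 0, 2)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    d <- abs(pts[a, ] - pts[b, ])
    if (all(d <= 1)) out <- rbind(out, c(a, b))
  }
  out
}

random_mask_chunk <- function(dims, p = 0.4, spacing = c(1, 1, 1),
                              seed = 1) {
  set.seed(seed)
  labels <- array(as.integer(runif(prod(dims)) < p), dims)
  seg_chunk(labels, spacing)
}

# Random rooted tree skeleton with scrambled ids.
random_skeleton <- function(n, seed = 1) {
  set.seed(seed)
  ids <- sample.int(10 * n, n)
  parent_idx <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                             integer(1)))
  skeleton(data.frame(
    id = ids,
    type = sample(0:4, n, replace = TRUE),
    x = round(runif(n, -500, 500), 3),
    y = round(runif(n, -500, 500), 3),
    z = round(runif(n, -500, 500), 3),
    radius = round(runif(n, 0, 20), 3),
    parent = c(-1L, ids[parent_idx[-1]])
  ))
}

# Unbranched chain skeleton through the given coordinates.
chain_skeleton <- function(coords, radius = 1, root_radius = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  radius <- rep_len(radius, n)
  if (!is.null(root_radius)) radius[1] <- root_radius
  skeleton(data.frame(
    id = seq_len(n), type = c(1L, rep(0L, n - 1L)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    radius = radius, parent = c(-1L, seq_len(n - 1L))
  ))
}

# Y-shaped skeleton: trunk along +x to the junction, two straight daughters.
y_skeleton <- function(trunk = 50, limb = 50, angle_deg = 90, step = 5,
                       radius = 1) {
  half <- angle_deg / 2 * pi / 180
  t1 <- seq(0, trunk, by = step)
  trunk_xyz <- cbind(t1, 0, 0)
  dirs <- list(c(cos(half), sin(half), 0), c(cos(half), -sin(half), 0))
  nodes <- trunk_xyz
  parent <- c(-1L, seq_len(nrow(trunk_xyz) - 1L))
  for (d in dirs) {
    tl <- seq(step, limb, by = step)
    limb_xyz <- sweep(outer(tl, d), 2, c(trunk, 0, 0), "+")
    first_parent <- nrow(trunk_xyz)
    start <- nrow(nodes)
    nodes <- rbind(nodes, limb_xyz)
    parent <- c(parent, first_parent,
                if (nrow(limb_xyz) > 1) start + seq_len(nrow(limb_xyz) - 1L))
  }
  n <- nrow(nodes)
  skeleton(data.frame(id = seq_len(n), type = c(1L, rep(0L, n - 1L)),
                      x = nodes[, 1], y = nodes[, 2], z = nodes[, 3],
                      radius = radius, parent = parent))
}

# Count branching nodes (>= 2 children) of a skeleton.
count_branch_nodes <- function(skel) {
  kids <- table(skel$parent[skel$parent != -1])
  sum(kids >= 2)
}

count_terminal_nodes <- function(skel) {
  sum(!(skel$id %in% skel$parent))
}

count_roots <- function(skel) sum(skel$parent == -1)

expect_valid_forest <- function(skel) {
  expect_s3_class(skel, "skeleton")
  expect_false(anyDuplicated(skel$id) > 0)
  nonroot <- skel$parent != -1
  expect_true(all(skel$parent[nonroot] %in% skel$id))
  # acyclic: walking up from every node terminates
  pidx <- match(skel$parent, skel$id)
  for (s in seq_len(nrow(skel))) {
    v <- s
    steps <- 0
    while (!is.na(v) && steps <= nrow(skel)) {
      v <- pidx[v]
      steps <- steps + 1
    }
    expect_true(is.na(v))
  }
}
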