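two_point_cloud <- function(p2) {
  point_cloud(rbind(c(0L, 0L, 0L), p2), spacing_nm = c(1, 1, 1),
              dbf_nm = c(2, 2))
}

test_that("edge weights are step length plus the center-hugging penalty", {
  g <- build_voxel_graph(two_point_cloud(c(1L, 0L, 0L)))
  expect_equal(unique(g$weight), 1.0)  # both at dbf_max: penalty 0

  gd <- build_voxel_graph(two_point_cloud(c(1L, 1L, 1L)))
  expect_equal(unique(gd$weight), sqrt(3))

  # Asymmetric penalty: stepping onto the low-dbf point costs more.
  cloud <- point_cloud(rbind(c(0L, 0L, 0L), c(1L, 0L, 0L)),
                       spacing_nm = c(1, 1, 1), dbf_nm = c(4, 2))
  p <- skeletonize_params(penalty_scale_nm = 100, penalty_exponent = 2)
  g2 <- build_voxel_graph(cloud, p)
  onto_low <- g2$weight[g2$to == 2]
  onto_high <- g2$weight[g2$to == 1]
  expect_equal(onto_low, 1 + 100 * (1 - 2 / 4)^2)
  expect_equal(onto_high, 1)
})

test_that("graph adjacency equals the brute-force 26-neighborhood scan", {
  chunk <- random_mask_chunk(c(6, 6, 6), p = 0.4, seed = 5)
  cloud <- compute_dbf(pack_mask(chunk, 1L))
  g <- build_voxel_graph(cloud)
  got <- unique(cbind(g$from, g$to))
  want <- brute_adjacency(cloud$points_vox)
  expect_identical(sort(paste(got[, 1], got[, 2])),
                   sort(paste(want[, 1], want[, 2])))
})

test_that("seed selection maximizes dbf with lexicographic tie-breaking", {
  cl <- point_cloud(rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(2L, 0L, 0L)),
                    spacing_nm = c(1, 1, 1), dbf_nm = c(1, 5, 3))
  expect_identical(find_seed(cl), 2L)
  tie <- point_cloud(rbind(c(0L, 0L, 0L), c(1L, 0L, 0L)),
                     spacing_nm = c(1, 1, 1), dbf_nm = c(2, 2))
  expect_identical(find_seed(tie), 1L)
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    pts <- matrix(sample.int(20, 3 * n, replace = TRUE), ncol = 3)
    pts <- unique(pts)
    dbf <- sample.int(5, nrow(pts), replace = TRUE)
    cl <- point_cloud(pts[order(pts[, 1], pts[, 2], pts[, 3]), ],
                      spacing_nm = c(1, 1, 1),
                      dbf_nm = dbf)
    expect_identical(cl$dbf_nm[find_seed(cl)], max(cl$dbf_nm))
  }
})

make_arc_graph <- function(n, from, to, w) {
  structure(list(n = n, from = from, to = to, weight = w),
            class = "voxel_graph")
}

test_that("single-source shortest paths are exact", {
  # path a-b-c with weights 1, 2
  g <- make_arc_graph(3L, c(1L, 2L, 2L, 3L), c(2L, 1L, 3L, 2L),
                      c(1, 1, 2, 2))
  sp <- graph_shortest_paths(g, 1L)
  expect_equal(sp$dist, c(0, 1, 3))
  expect_identical(sp$pred[3], 2L)
  expect_identical(sp$pred[2], 1L)

  # triangle ab=1, bc=1, ac=3
  tg <- make_arc_graph(3L,
                       c(1L, 2L, 2L, 3L, 1L, 3L),
                       c(2L, 1L, 3L, 2L, 3L, 1L),
                       c(1, 1, 1, 1, 3, 3))
  expect_equal(graph_shortest_paths(tg, 1L)$dist[3], 2)

  expect_error(graph_shortest_paths(g, 5L),
               class = "skelemorph_index_error")
})

test_that("dijkstra distances match the Bellman-Ford oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30L
    m <- 90L
    from <- sample.int(n, m, replace = TRUE)
    to <- sample.int(n, m, replace = TRUE)
    keep <- from != to
    w <- round(runif(sum(keep), 0.1, 10), 3)
    g <- make_arc_graph(n, from[keep], to[keep], w)
    src <- sample.int(n, 1)
    expect_equal(graph_shortest_paths(g, src)$dist,
                 bellman_ford(n, g$from, g$to, g$weight, src),
                 tolerance = 1e-9)
  }
})

test_that("a single voxel traces to a one-node skeleton with dbf radius", {
  chunk <- seg_chunk(array(1L, c(1, 1, 1)), c(5, 5, 45))
  skel <- trace_skeleton(compute_dbf(pack_mask(chunk, 1L)))
  expect_identical(nrow(skel), 1L)
  expect_identical(skel$parent, -1L)
  expect_equal(skel$radius, 5)
})

test_that("the cylinder phantom traces to an unbranched axial skeleton", {
  ph <- make_cylinder(40, 3, c(1, 1, 1))
  cloud <- compute_dbf(pack_mask(ph$chunk, 1L))
  skel <- trace_skeleton(cloud)
  expect_identical(count_roots(skel), 1L)
  expect_identical(count_branch_nodes(skel), 0L)
  axis_yz <- ph$truth$centerline_nm[1, 2:3]
  dev <- sqrt(rowSums(sweep(as.matrix(skel[, c("y", "z")]), 2,
                            axis_yz, "-")^2))
  expect_lt(mean(dev), sqrt(3))
  truth_len <- 40
  expect_lt(abs(total_path_length(skel) - truth_len) / truth_len, 0.1)
  # radius equals the voxel dbf and every node voxel is in the cloud
  pos <- sweep(as.matrix(skel[, c("x", "y", "z")]), 2,
               cloud$spacing_nm, "/") - 0.5
  key <- paste(round(pos[, 1]), round(pos[, 2]), round(pos[, 3]))
  cloud_key <- paste(cloud$points_vox[, 1], cloud$points_vox[, 2],
                     cloud$points_vox[, 3])
  idx <- match(key, cloud_key)
  expect_false(anyNA(idx))
  expect_equal(skel$radius, cloud$dbf_nm[idx])
})

test_that("tracing is deterministic", {
  ph <- make_y(60, trunk_vox = 20, limb_vox = 20, radius_vox = 2)
  cloud <- compute_dbf(pack_mask(ph$chunk, 1L))
  s1 <- trace_skeleton(cloud)
  s2 <- trace_skeleton(cloud)
  expect_identical(s1, s2)
})

test_that("reconnection bridges gaps within the threshold, ascending", {
  frag <- function(x0, n = 5, step = 2) {
    coords <- cbind(x0 + step * (seq_len(n) - 1), 0, 0)
    chain_skeleton(coords)
  }
  merge_forest <- function(parts) {
    offset <- 0L
    rows <- lapply(parts, function(p) {
      p$id <- p$id + offset
      p$parent <- ifelse(p$parent == -1L, -1L, p$parent + offset)
      offset <<- offset + max(p$id)
      as.data.frame(p)
    })
    skeleton(do.call(rbind, rows))
  }
  two <- merge_forest(list(frag(0), frag(18)))  # tips at x=8 and 18: gap 10
  expect_identical(count_roots(reconnect_components(two, 20)), 1L)
  two_far <- merge_forest(list(frag(0), frag(38)))  # gap 30
  expect_identical(count_roots(reconnect_components(two_far, 20)), 2L)

  # three fragments with gaps 5 and 8: both joined under threshold 10,
  # only the 5 nm gap under threshold 6 (greedy ascending order)
  three <- merge_forest(list(frag(0), frag(13), frag(29)))
  expect_identical(count_roots(reconnect_components(three, 10)), 1L)
  partial <- reconnect_components(three, 6)
  expect_identical(count_roots(partial), 2L)
  expect_valid_forest(partial)
})

test_that("a connected cloud reconnected at infinite threshold has one root", {
  chunk <- random_mask_chunk(c(5, 5, 5), p = 0.9, seed = 3)
  skel <- trace_skeleton(compute_dbf(pack_mask(chunk, 1L)))
  skel <- reconnect_components(skel, Inf)
  expect_identical(count_roots(skel), 1L)
  expect_valid_forest(skel)
})
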