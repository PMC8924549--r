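test_that("coincident consecutive nodes are merged and children re-parented", {
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 0, 0), c(20, 0, 0))
  skel <- chain_skeleton(coords, radius = c(1, 2, 1, 1))
  out <- remove_redundant_nodes(skel, eps_nm = 0.5)
  expect_identical(nrow(out), 3L)
  expect_valid_forest(out)
  # the larger-radius node of the coincident pair survives
  expect_true(2 %in% out$radius)
  # chain stays connected end to end
  expect_equal(total_path_length(out), 20)
})

test_that("chains with all gaps above eps are untouched", {
  skel <- chain_skeleton(cbind(seq(0, 50, by = 5), 0, 0))
  expect_identical(remove_redundant_nodes(skel, eps_nm = 2), skel)
})

test_that("redundant-node removal matches the greedy merge oracle", {
  greedy_keep <- function(P, radius, eps) {
    m <- nrow(P)
    kept <- 1L
    for (i in 2:(m - 1L)) {
      last <- kept[length(kept)]
      if (sqrt(sum((P[last, ] - P[i, ])^2)) < eps) {
        if (last != 1L && radius[i] > radius[last])
          kept[length(kept)] <- i
      } else {
        kept <- c(kept, i)
      }
    }
    last <- kept[length(kept)]
    if (last != 1L && sqrt(sum((P[last, ] - P[m, ])^2)) < eps)
      kept <- kept[-length(kept)]
    c(kept, m)
  }
  for (seed in 1:10) {
    set.seed(seed)
    n <- 25L
    steps <- runif(n - 1, 0, 3)
    P <- cbind(cumsum(c(0, steps)), 0, 0)
    radius <- runif(n, 0.5, 3)
    skel <- chain_skeleton(P, radius = radius)
    out <- remove_redundant_nodes(skel, eps_nm = 1.5)
    expect_identical(nrow(out), length(greedy_keep(P, radius, 1.5)))
    expect_valid_forest(out)
  }
})

test_that("hair shorter than the attachment diameter ratio is shaved", {
  # trunk 0..100, branch node at 100 with radius 50, long limb + short hair
  nodes <- data.frame(
    id = 1:6, type = c(1L, rep(0L, 5)),
    x = c(0, 50, 100, 200, 300, 110),
    y = c(0, 0, 0, 0, 0, 10),
    z = 0,
    radius = c(60, 5, 50, 5, 5, 1),
    parent = c(-1L, 1L, 2L, 3L, 4L, 3L)
  )
  skel <- skeleton(nodes)
  out <- remove_hair(skel, hair_ratio = 1.5)
  # hair (length ~20 < 1.5 * 100) gone, long limb kept
  expect_false(6L %in% out$id)
  expect_true(5L %in% out$id)

  # a 200 nm terminal segment on the same node survives
  nodes$x[6] <- 300
  nodes$y[6] <- 50
  keep <- remove_hair(skeleton(nodes), hair_ratio = 1.5)
  expect_true(6L %in% keep$id)

  unbranched <- chain_skeleton(cbind(0:5, 0, 0))
  expect_identical(remove_hair(unbranched, 1.5), unbranched)
})

test_that("branches inside the soma sphere are removed, exiting ones kept", {
  # root radius 20; a stub subtree entirely inside, a limb extending far out
  nodes <- data.frame(
    id = 1:7, type = c(1L, rep(0L, 6)),
    x = c(0, 10, 5, 8, 30, 60, 90),
    y = c(0, 0, 5, 9, 0, 0, 0),
    z = 0,
    radius = c(20, 2, 1, 1, 2, 2, 2),
    parent = c(-1L, 1L, 2L, 3L, 2L, 5L, 6L)
  )
  skel <- skeleton(nodes)
  out <- remove_soma_branches(skel)
  expect_false(any(c(3L, 4L) %in% out$id))  # stub inside the sphere
  expect_true(all(c(2L, 5L, 6L, 7L) %in% out$id))  # exits the sphere

  zero <- skel
  zero$radius[1] <- 0
  expect_identical(remove_soma_branches(skeleton(zero)), skeleton(zero))
})

test_that("resampling re-parameterizes segments by arc length", {
  skel <- chain_skeleton(cbind(seq(0, 100, by = 4), 0, 0))
  out <- resample_skeleton(skel, 10)
  expect_identical(nrow(out), 11L)
  expect_equal(sort(out$x), seq(0, 100, by = 10))
  expect_equal(total_path_length(out), 100)

  coarse <- resample_skeleton(skel, 1000)
  expect_identical(nrow(coarse), 2L)
  expect_equal(sort(coarse$x), c(0, 100))
  expect_valid_forest(coarse)

  # irreducible positions preserved exactly on a Y
  y <- y_skeleton()
  ry <- resample_skeleton(y, 7)
  expect_true(all(c(0) %in% ry$x))
  expect_equal(total_path_length(ry), total_path_length(y),
               tolerance = 1e-9)
})

test_that("zero-length terminal branches are deleted idempotently", {
  nodes <- data.frame(
    id = 1:5, type = c(1L, rep(0L, 4)),
    x = c(0, 10, 20, 10, 10),
    y = c(0, 0, 0, 0, 0),
    z = 0, radius = 1,
    parent = c(-1L, 1L, 2L, 2L, 4L)
  )
  skel <- skeleton(nodes)  # nodes 4-5 coincide with branch node 2
  out <- remove_empty_branches(skel)
  expect_false(any(c(4L, 5L) %in% out$id))
  expect_identical(remove_empty_branches(out), out)

  y <- y_skeleton()
  expect_identical(remove_empty_branches(y), y)
})

test_that("smoothing averages interiors and pins endpoints", {
  straight <- chain_skeleton(cbind(0:10, 0, 0))
  out <- smooth_skeleton(straight, 3)
  expect_equal(as.matrix(out[, c("x", "y", "z")]),
               as.matrix(straight[, c("x", "y", "z")]), tolerance = 1e-9)

  zig <- chain_skeleton(cbind(0:4, c(0, 0, 1, 0, 0), 0))
  sm <- smooth_skeleton(zig, 3)
  expect_equal(sm$y[3], 1 / 3)
  expect_equal(sm$y[c(1, 5)], c(0, 0))
  expect_equal(sm$x[c(1, 5)], c(0, 4))
})

test_that("every cleanup op preserves forest invariants on random trees", {
  for (seed in 1:5) {
    skel <- random_skeleton(30, seed = seed)
    ops <- list(
      function(s) remove_redundant_nodes(s, 5),
      function(s) remove_hair(s, 1.5),
      remove_soma_branches,
      function(s) resample_skeleton(s, 50),
      remove_empty_branches,
      function(s) smooth_skeleton(s, 3)
    )
    for (op in ops) {
      out <- op(skel)
      expect_valid_forest(out)
    }
  }
})

test_that("cleanup ops are idempotent on their own output", {
  skel <- random_skeleton(40, seed = 99)
  a <- remove_hair(skel, 1.5)
  expect_identical(remove_hair(a, 1.5), a)
  b <- remove_soma_branches(skel)
  expect_identical(remove_soma_branches(b), b)
  c1 <- remove_empty_branches(skel)
  expect_identical(remove_empty_branches(c1), c1)
  d <- remove_redundant_nodes(skel, 5)
  expect_identical(remove_redundant_nodes(d, 5), d)
})

test_that("the full pipeline keeps the extremal nodes of a straight path", {
  skel <- chain_skeleton(cbind(seq(0, 100, by = 2), 0, 0))
  out <- postprocess(skel, postprocess_params(resample_spacing_nm = 10,
                                              redundant_eps_nm = 1))
  expect_equal(min(out$x), 0)
  expect_equal(max(out$x), 100)
  expect_valid_forest(out)
})
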