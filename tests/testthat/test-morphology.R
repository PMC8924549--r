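test_that("a Y decomposes into 3 segments with orders 0,1,1", {
  y <- y_skeleton()
  d <- decompose_skeleton(y)
  expect_identical(length(d$paths), 3L)
  expect_identical(sort(d$order), c(0L, 1L, 1L))
  expect_identical(sum(d$is_terminal), 2L)

  straight <- chain_skeleton(cbind(0:10, 0, 0))
  ds <- decompose_skeleton(straight)
  expect_identical(length(ds$paths), 1L)
  expect_identical(ds$order, 0L)
})

test_that("segments partition the edge set on random trees", {
  for (seed in 1:10) {
    skel <- random_skeleton(sample(5:40, 1), seed = 200 + seed)
    d <- decompose_skeleton(skel)
    seg_edges <- sum(lengths(d$paths) - 1L)
    expect_identical(seg_edges, nrow(skel) - 1L)
    # every node appears in some segment
    expect_setequal(unique(unlist(d$paths)), seq_len(nrow(skel)))
  }
})

test_that("tortuosity is path over chord", {
  straight <- chain_skeleton(cbind(seq(0, 50, 10), 0, 0))
  sf <- segment_features(decompose_skeleton(straight))
  expect_equal(sf$tortuosity, 1.0)

  l_shape <- chain_skeleton(rbind(c(0, 0, 0), c(30, 0, 0), c(30, 40, 0)))
  sf2 <- segment_features(decompose_skeleton(l_shape))
  expect_equal(sf2$tortuosity, 70 / 50)
  expect_equal(sf2$path_length_nm, 70)

  # semicircular arc: path pi*r over chord 2r -> pi/2
  n <- 1000
  theta <- seq(0, pi, length.out = n + 1)
  arc <- chain_skeleton(cbind(cos(theta), sin(theta), 0) * 100)
  sf3 <- segment_features(decompose_skeleton(arc))
  expect_equal(sf3$tortuosity, pi / 2, tolerance = 1e-6)

  # zero chord: closed loop path -> tortuosity undefined
  loop <- chain_skeleton(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0),
                               c(0, 0, 0)))
  expect_true(is.na(segment_features(decompose_skeleton(loop))$tortuosity))
})

test_that("branching angles come from daughter directions at the junction", {
  y <- y_skeleton(angle_deg = 90)
  sf <- segment_features(decompose_skeleton(y))
  trunk <- which(!sf$is_terminal)
  expect_equal(sf$branching_angle_rad[trunk], pi / 2, tolerance = 1e-9)
  expect_true(all(is.na(sf$branching_angle_rad[sf$is_terminal])))

  y2 <- y_skeleton(angle_deg = 60)
  sf2 <- segment_features(decompose_skeleton(y2))
  expect_equal(sf2$branching_angle_rad[!sf2$is_terminal], pi / 3,
               tolerance = 1e-9)
})

test_that("distance to root accumulates along parent segments", {
  y <- y_skeleton(trunk = 50, limb = 50)
  sf <- segment_features(decompose_skeleton(y))
  expect_equal(sort(sf$dist_to_root_nm), c(0, 50, 50))
})

test_that("the neck/head ratio splits terminal segments at mid arc", {
  radii <- c(5, 5, 1, 1, 4, 4, 5)  # thin neck then bulbous head
  coords <- cbind(seq(0, 60, by = 10), 0, 0)
  skel <- chain_skeleton(coords, radius = radii)
  sf <- segment_features(decompose_skeleton(skel))
  expect_equal(sf$neck_head_ratio, 1 / 5)
})

test_that("sholl counts sphere crossings from the root", {
  line <- chain_skeleton(cbind(seq(0, 100, by = 1) * 1000, 0, 0))
  counts <- sholl(line, seq(10, 90, by = 10) * 1000)
  expect_identical(counts, rep(1L, 9))

  y <- y_skeleton(trunk = 50, limb = 60, angle_deg = 90, step = 1)
  expect_identical(sholl(y, c(25, 80)), c(1L, 2L))
  expect_identical(sholl(y, 1e6), 0L)
})

test_that("fractal dimension separates lines from filled squares", {
  line <- cbind(seq(0, 1, length.out = 1000), 0, 0)
  expect_equal(fractal_dimension(line), 1.0, tolerance = 0.15)

  g <- expand.grid(x = seq_len(64), y = seq_len(64))
  square <- cbind(g$x, g$y, 0)
  expect_equal(fractal_dimension(square), 2.0, tolerance = 0.2)

  expect_true(is.na(fractal_dimension(cbind(1:10, 0, 0))))
  expect_true(is.na(fractal_dimension(matrix(1, 40, 3))))
})

test_that("frustum surface area matches the closed form", {
  cyl <- chain_skeleton(rbind(c(0, 0, 0), c(10, 0, 0)), radius = 1)
  expect_equal(surface_area(cyl), 2 * pi * 10)
  # cone: r 3 -> 0 over length 4, slant 5
  cone <- chain_skeleton(rbind(c(0, 0, 0), c(4, 0, 0)), radius = c(3, 0))
  expect_equal(surface_area(cone), pi * 3 * 5)
})

test_that("whole-neuron features follow their definitions", {
  single <- chain_skeleton(rbind(c(0, 0, 0), c(30, 0, 0)))
  f <- neuron_features(single)
  expect_equal(f$total_path_length_nm, 30)
  expect_identical(f$n_branching_points, 0L)
  expect_equal(f$longest_segment_nm, 30)

  # symmetric cross centered on the root: asymmetry 0, typical radius 5
  cross <- skeleton(data.frame(
    id = 1:5, type = c(1L, rep(0L, 4)),
    x = c(0, 5, -5, 0, 0), y = c(0, 0, 0, 5, -5), z = 0,
    radius = 1, parent = c(-1L, 1L, 1L, 1L, 1L)
  ))
  fc <- neuron_features(cross)
  expect_equal(fc$asymmetry_nm, 0, tolerance = 1e-12)
  expect_equal(fc$soma_to_mass_center_nm, fc$asymmetry_nm)
  expect_equal(fc$typical_radius_nm, sqrt(mean(c(0, 25, 25, 25, 25))))

  y <- y_skeleton()
  fy <- neuron_features(y)
  expect_identical(fy$n_branching_points, 1L)
  expect_equal(fy$median_segment_length_nm, 50)
  expect_true(fy$mean_tortuosity >= 1)
})

test_that("synapse counts join the feature vector when a table is given", {
  syn <- synapse_table(data.frame(
    synapse_id = 1:5, presyn = c(1, 1, 2, 2, 2), postsyn = c(2, 2, 1, 3, 3),
    x_nm = 0, y_nm = 0, z_nm = 0
  ))
  f <- neuron_features(chain_skeleton(cbind(0:3, 0, 0)), synapses = syn,
                       neuron_id = 2)
  expect_identical(f$n_presynapses, 3L)
  expect_identical(f$n_postsynapses, 2L)

  tab <- neuron_feature_table(list(`1` = y_skeleton(),
                                   `2` = chain_skeleton(cbind(0:9, 0, 0))),
                              synapses = syn)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$n_presynapses, c(2L, 3L))
})
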