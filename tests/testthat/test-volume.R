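test_that("bit-packing payload is 1 bit per voxel with the 8-fold ratio", {
  chunk <- seg_chunk(array(1L, c(64, 64, 64)), c(5, 5, 45))
  m <- pack_mask(chunk, 1L)
  expect_identical(length(m$bits), 32768L)
  expect_identical(prod(m$dims) / length(m$bits), 8)

  tiny <- seg_chunk(array(c(1L, 0L, 1L), c(3, 1, 1)), c(1, 1, 1))
  expect_identical(length(pack_mask(tiny, 1L)$bits), 1L)
})

test_that("background id is rejected", {
  chunk <- seg_chunk(array(1L, c(2, 2, 2)), c(1, 1, 1))
  expect_error(pack_mask(chunk, 0), "background")
})

test_that("pack/unpack round trip is lossless on random masks", {
  for (seed in 1:20) {
    set.seed(seed)
    dims <- sample(1:10, 3, replace = TRUE)
    chunk <- random_mask_chunk(dims, p = runif(1, 0.1, 0.9), seed = seed)
    m <- pack_mask(chunk, 1L)
    expect_identical(length(m$bits), as.integer(ceiling(prod(dims) / 8)))
    expect_identical(unpack_mask(m), chunk$labels == 1L)
  }
})

test_that("point cloud extraction applies offsets and lexicographic order", {
  lab <- array(1L, c(2, 1, 1))
  chunk <- seg_chunk(lab, c(1, 1, 1), offset_vox = c(10L, 0L, 0L))
  cloud <- extract_point_cloud(pack_mask(chunk, 1L))
  expect_identical(cloud$points_vox,
                   matrix(c(10L, 11L, 0L, 0L, 0L, 0L), ncol = 3))

  empty <- seg_chunk(array(0L, c(3, 3, 3)), c(1, 1, 1))
  expect_identical(n_points(extract_point_cloud(pack_mask(empty, 1L))), 0L)

  chunk8 <- random_mask_chunk(c(8, 8, 8), seed = 42)
  m <- pack_mask(chunk8, 1L)
  cloud8 <- extract_point_cloud(m)
  expect_identical(n_points(cloud8), mask_popcount(m))
  expect_identical(n_points(cloud8), sum(chunk8$labels == 1L))
  o <- order(cloud8$points_vox[, 1], cloud8$points_vox[, 2],
             cloud8$points_vox[, 3])
  expect_identical(o, seq_len(n_points(cloud8)))
})

test_that("dbf matches the nearest-background-center convention on knowns", {
  cube <- seg_chunk(array(1L, c(3, 3, 3)), c(1, 1, 1))
  cloud <- compute_dbf(pack_mask(cube, 1L))
  center <- which(apply(cloud$points_vox, 1, function(p) all(p == 1)))
  corner <- which(apply(cloud$points_vox, 1, function(p) all(p == 0)))
  expect_equal(cloud$dbf_nm[center], 2.0)
  expect_equal(cloud$dbf_nm[corner], 1.0)

  single <- seg_chunk(array(1L, c(1, 1, 1)), c(5, 5, 45))
  expect_equal(compute_dbf(pack_mask(single, 1L))$dbf_nm, 5.0)

  empty <- seg_chunk(array(0L, c(2, 2, 2)), c(1, 1, 1))
  expect_error(compute_dbf(pack_mask(empty, 1L)),
               class = "skelemorph_empty_object")
})

test_that("dbf equals the brute-force oracle, including anisotropy", {
  cases <- list(
    list(dims = c(6, 6, 6), spacing = c(1, 1, 1), seed = 1),
    list(dims = c(12, 9, 5), spacing = c(1, 1, 1), seed = 2),
    list(dims = c(8, 8, 4), spacing = c(5, 5, 45), seed = 3),
    list(dims = c(10, 4, 7), spacing = c(2, 3, 10), seed = 4)
  )
  for (cs in cases) {
    chunk <- random_mask_chunk(cs$dims, p = 0.5, spacing = cs$spacing,
                               seed = cs$seed)
    if (!any(chunk$labels == 1L)) next
    cloud <- compute_dbf(pack_mask(chunk, 1L))
    expect_equal(cloud$dbf_nm, brute_dbf(chunk$labels == 1L, cs$spacing),
                 tolerance = 1e-12)
  }
})

test_that("dbf is monotone under erosion of the foreground", {
  chunk <- random_mask_chunk(c(10, 10, 10), p = 0.7, seed = 9)
  cloud <- compute_dbf(pack_mask(chunk, 1L))
  set.seed(10)
  eroded <- chunk$labels
  fg <- which(eroded == 1L)
  eroded[sample(fg, length(fg) %/% 3)] <- 0L
  cloud2 <- compute_dbf(pack_mask(seg_chunk(eroded, chunk$spacing_nm), 1L))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  shared <- match(key(cloud2$points_vox), key(cloud$points_vox))
  expect_true(all(cloud2$dbf_nm <= cloud$dbf_nm[shared] + 1e-12))
})

test_that("seg chunks survive the sparse text serialization", {
  chunk <- random_mask_chunk(c(7, 5, 3), p = 0.3, spacing = c(5, 5, 45),
                             seed = 11)
  chunk$labels[1, 1, 1] <- 7L
  path <- withr::local_tempfile(fileext = ".seg.tsv")
  write_seg_tsv(chunk, path)
  back <- read_seg_tsv(path)
  expect_identical(back$labels, chunk$labels)
  expect_equal(back$spacing_nm, chunk$spacing_nm)
  expect_identical(back$offset_vox, chunk$offset_vox)
})
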