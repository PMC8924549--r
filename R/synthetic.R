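# Synthetic phantoms with exact ground truth, and circuits with planted
# structure. Every generator is deterministic under its seed.

new_phantom <- function(chunk, truth, params, seed) {
  structure(list(chunk = chunk, truth = truth, params = params,
                 rng_seed = as.integer(seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels, %d foreground, truth: %s\n",
              paste(dim(x$chunk$labels), collapse = "x"),
              sum(x$chunk$labels != 0L),
              paste(names(x$truth), collapse = ", ")))
  invisible(x)
}

# Label voxels whose center lies within `radius_vox` (voxel units) of any
# of the given line segments (list of 2 x 3 matrices, continuous voxel
# coordinates where a voxel center sits at index + 0.5).
rasterize_tubes <- function(dims, segments, radius_vox) {
  centers <- as.matrix(expand.grid(x = seq_len(dims[1L]) - 0.5,
                                   y = seq_len(dims[2L]) - 0.5,
                                   z = seq_len(dims[3L]) - 0.5))
  inside <- rep(FALSE, nrow(centers))
  for (seg in segments) {
    a <- seg[1L, ]
    b <- seg[2L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(centers, 2L, a, "-")
    t <- if (len2 > 0) pmin(1, pmax(0, (rel %*% ab) / len2)) else
      matrix(0, nrow(centers), 1L)
    closest <- rel - t %*% t(ab)
    inside <- inside | rowSums(closest^2) <= radius_vox^2
  }
  array(as.integer(inside), dim = dims)
}

#' Cylinder phantom
#'
#' A solid tube of the given radius along one axis, with ground-truth
#' centerline (axis polyline in nm) and topology (0 branching nodes, 2
#' terminals). The foreground voxel count is within 10% of
#' `pi * r^2 * L`.
#'
#' @param length_vox Tube length in voxels (>= 10 * radius).
#' @param radius_vox Tube radius in voxels (>= 2).
#' @param spacing_nm Voxel size, nm.
#' @param axis Axis of the tube: `"x"`, `"y"` or `"z"`.
#' @param seed RNG seed (recorded; the cylinder itself is deterministic).
#' @return A `phantom`: `chunk` ([seg_chunk()], object id 1), `truth`
#'   (centerline polyline in nm, expected topology), `params`, `rng_seed`.
#' @export
make_cylinder <- function(length_vox = 100L, radius_vox = 4L,
                          spacing_nm = c(1, 1, 1), axis = "x", seed = 1L) {
  if (radius_vox < 2L) stop("`radius_vox` must be >= 2")
  if (length_vox < 10L * radius_vox)
    stop("`length_vox` must be >= 10 * radius_vox")
  margin <- 1L
  side <- 2L * radius_vox + 2L * margin + 1L
  c_perp <- radius_vox + margin + 0.5
  dims <- c(length_vox + 2L * margin, side, side)
  # Flat-ended tube: perpendicular distance <= r, axial extent [margin, margin + L].
  centers <- as.matrix(expand.grid(x = seq_len(dims[1L]) - 0.5,
                                   y = seq_len(dims[2L]) - 0.5,
                                   z = seq_len(dims[3L]) - 0.5))
  inside <- (centers[, 2L] - c_perp)^2 + (centers[, 3L] - c_perp)^2 <=
    radius_vox^2 &
    centers[, 1L] >= margin & centers[, 1L] <= margin + length_vox
  labels <- array(as.integer(inside), dim = dims)
  truth_line <- rbind(c(margin, c_perp, c_perp),
                      c(margin + length_vox, c_perp, c_perp))
  perm <- switch(axis, x = c(1L, 2L, 3L), y = c(2L, 1L, 3L),
                 z = c(3L, 2L, 1L), stop("`axis` must be x, y or z"))
  labels <- aperm(labels, perm)
  truth_line <- truth_line[, perm, drop = FALSE]
  spacing_nm <- check_len3_positive(spacing_nm, "spacing_nm")
  chunk <- seg_chunk(labels, spacing_nm)
  new_phantom(
    chunk,
    truth = list(centerline_nm = sweep(truth_line, 2L, spacing_nm, "*"),
                 n_branch = 0L, n_terminal = 2L),
    params = list(length_vox = length_vox, radius_vox = radius_vox,
                  axis = axis),
    seed = seed
  )
}

#' Y-junction phantom
#'
#' A trunk along +x splitting into two limbs separated by `limb_angle_deg`
#' in the xy-plane. Ground truth: one branching node at the recorded
#' position, three terminals, the requested angle.
#'
#' @param limb_angle_deg Full angle between the two limbs, degrees.
#' @param trunk_vox,limb_vox Trunk and limb lengths, voxels.
#' @param radius_vox Tube radius, voxels.
#' @param spacing_nm Voxel size, nm.
#' @param seed Recorded seed.
#' @return A `phantom`.
#' @export
make_y <- function(limb_angle_deg = 90, trunk_vox = 40L, limb_vox = 40L,
                   radius_vox = 3L, spacing_nm = c(1, 1, 1), seed = 1L) {
  half <- limb_angle_deg / 2 * pi / 180
  margin <- radius_vox + 2
  branch <- c(margin + trunk_vox, 0, 0)
  tip1 <- branch + limb_vox * c(cos(half), sin(half), 0)
  tip2 <- branch + limb_vox * c(cos(half), -sin(half), 0)
  ylo <- min(0, tip1[2L], tip2[2L]) - margin
  yhi <- max(0, tip1[2L], tip2[2L]) + margin
  shift <- c(0, -ylo, margin)
  segs <- lapply(list(rbind(c(margin, 0, 0), branch),
                      rbind(branch, tip1), rbind(branch, tip2)),
                 function(s) sweep(s, 2L, shift, "+"))
  dims <- c(ceiling(max(tip1[1L], tip2[1L]) + margin),
            ceiling(yhi - ylo), 2L * margin)
  labels <- rasterize_tubes(dims, segs, radius_vox)
  spacing_nm <- check_len3_positive(spacing_nm, "spacing_nm")
  chunk <- seg_chunk(labels, spacing_nm)
  new_phantom(
    chunk,
    truth = list(branch_nm = (branch + shift) * spacing_nm,
                 angle_rad = 2 * half, n_branch = 1L, n_terminal = 3L),
    params = list(limb_angle_deg = limb_angle_deg, trunk_vox = trunk_vox,
                  limb_vox = limb_vox, radius_vox = radius_vox),
    seed = seed
  )
}

#' Broken tube phantom
#'
#' A straight tube with a gap of `gap_vox` voxels removed from the middle:
#' two components whose nearest foreground voxels are about the requested
#' gap apart, for exercising fragment reconnection.
#'
#' @param gap_vox Gap length along the axis, voxels.
#' @param length_vox,radius_vox Tube dimensions, voxels.
#' @param spacing_nm Voxel size, nm.
#' @param seed Recorded seed.
#' @return A `phantom` with `truth$gap_nm` and `truth$n_components = 2`.
#' @export
make_broken_tube <- function(gap_vox = 10L, length_vox = 60L,
                             radius_vox = 3L, spacing_nm = c(1, 1, 1),
                             seed = 1L) {
  ph <- make_cylinder(length_vox, radius_vox, spacing_nm, axis = "x",
                      seed = seed)
  labels <- ph$chunk$labels
  margin <- 1L
  x0 <- margin + (length_vox - gap_vox) / 2
  xc <- seq_len(dim(labels)[1L]) - 0.5
  blank <- xc > x0 & xc < x0 + gap_vox
  labels[blank, , ] <- 0L
  chunk <- seg_chunk(labels, ph$chunk$spacing_nm)
  new_phantom(
    chunk,
    truth = list(gap_nm = gap_vox * spacing_nm[1L], n_components = 2L,
                 centerline_nm = ph$truth$centerline_nm),
    params = c(ph$params, list(gap_vox = gap_vox)),
    seed = seed
  )
}

#' Star phantom
#'
#' `n_rays` straight tubes radiating from a common center in the xy-plane:
#' one branching center, `n_rays` terminals, for Sholl and topology tests.
#'
#' @param n_rays Number of rays (>= 3).
#' @param ray_vox Ray length, voxels.
#' @param radius_vox Tube radius, voxels.
#' @param spacing_nm Voxel size, nm.
#' @param seed Recorded seed.
#' @return A `phantom`.
#' @export
make_star <- function(n_rays = 5L, ray_vox = 30L, radius_vox = 3L,
                      spacing_nm = c(1, 1, 1), seed = 1L) {
  if (n_rays < 3L) stop("`n_rays` must be >= 3")
  margin <- radius_vox + 2
  half_side <- ray_vox + margin
  center <- c(half_side, half_side, margin)
  angles <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  segs <- lapply(angles, function(a)
    rbind(center, center + ray_vox * c(cos(a), sin(a), 0)))
  dims <- c(2L * half_side, 2L * half_side, 2L * margin)
  labels <- rasterize_tubes(dims, segs, radius_vox)
  spacing_nm <- check_len3_positive(spacing_nm, "spacing_nm")
  chunk <- seg_chunk(labels, spacing_nm)
  new_phantom(
    chunk,
    truth = list(center_nm = center * spacing_nm, n_branch = 1L,
                 n_terminal = as.integer(n_rays)),
    params = list(n_rays = n_rays, ray_vox = ray_vox,
                  radius_vox = radius_vox),
    seed = seed
  )
}

#' Soma-with-neurites phantom
#'
#' A sphere (cell body) with thin straight neurites radiating from it, for
#' exercising soma-branch removal and root placement. The soma center and
#' radius are recorded as ground truth.
#'
#' @param soma_radius_vox Soma radius, voxels.
#' @param n_neurites Number of neurites.
#' @param neurite_vox Neurite length beyond the soma surface, voxels.
#' @param neurite_radius_vox Neurite radius, voxels.
#' @param spacing_nm Voxel size, nm.
#' @param seed Recorded seed.
#' @return A `phantom`.
#' @export
make_soma_with_neurites <- function(soma_radius_vox = 8L, n_neurites = 3L,
                                    neurite_vox = 30L,
                                    neurite_radius_vox = 2L,
                                    spacing_nm = c(1, 1, 1), seed = 1L) {
  margin <- neurite_radius_vox + 2
  half_side <- soma_radius_vox + neurite_vox + margin
  center <- rep(half_side, 3L)
  angles <- 2 * pi * (seq_len(n_neurites) - 1L) / n_neurites
  segs <- lapply(angles, function(a)
    rbind(center,
          center + (soma_radius_vox + neurite_vox) * c(cos(a), sin(a), 0)))
  dims <- rep(2L * half_side, 3L)
  dims[3L] <- 2L * (max(soma_radius_vox, neurite_radius_vox) + margin)
  center[3L] <- dims[3L] / 2
  segs <- lapply(segs, function(s) { s[, 3L] <- center[3L]; s })
  labels <- rasterize_tubes(dims, segs, neurite_radius_vox)
  centers <- as.matrix(expand.grid(x = seq_len(dims[1L]) - 0.5,
                                   y = seq_len(dims[2L]) - 0.5,
                                   z = seq_len(dims[3L]) - 0.5))
  soma <- rowSums(sweep(centers, 2L, center, "-")^2) <= soma_radius_vox^2
  labels[soma] <- 1L
  spacing_nm <- check_len3_positive(spacing_nm, "spacing_nm")
  chunk <- seg_chunk(labels, spacing_nm)
  new_phantom(
    chunk,
    truth = list(soma_center_nm = center * spacing_nm,
                 soma_radius_nm = soma_radius_vox * min(spacing_nm),
                 n_terminal = as.integer(n_neurites)),
    params = list(soma_radius_vox = soma_radius_vox,
                  n_neurites = n_neurites, neurite_vox = neurite_vox),
    seed = seed
  )
}

# Archetype skeleton for class `cls` (of n_classes): classes sit in
# well-separated spatial territories and bend differently, giving
# NBLAST-separable types. Coordinates in nm.
class_archetype <- function(cls, n_classes, n_nodes = 41L,
                            step_um = 2, radius_nm = 500) {
  theta <- 2 * pi * (cls - 1L) / n_classes
  center <- 150e3 * c(cos(theta), sin(theta), 0)  # 150 um apart
  d1 <- c(cos(theta + pi / 3), sin(theta + pi / 3), 0)
  d2 <- c(0, 0, 1)
  t <- seq_len(n_nodes) - 1L
  bend <- 20e3 * cls / n_classes
  P <- sweep(outer(t * step_um * 1e3, d1) +
               outer(bend * sin(t / (n_nodes - 1L) * pi), d2),
             2L, center, "+")
  skeleton(data.frame(
    id = seq_len(n_nodes), type = c(1L, rep(0L, n_nodes - 1L)),
    x = P[, 1L], y = P[, 2L], z = P[, 3L],
    radius = radius_nm,
    parent = c(-1L, seq_len(n_nodes - 1L))
  ), validate = FALSE)
}

#' Synthetic circuit with planted classes and connectivity
#'
#' Neurons are jittered copies of per-class archetype skeletons living in
#' separated spatial territories (so morphological classes are recoverable
#' by NBLAST), and the synapse count of every ordered neuron pair is drawn
#' as Poisson with rate `lambda_within` inside a class and `lambda_between`
#' across classes (planted community structure).
#'
#' @param n_neurons Number of neurons.
#' @param n_classes Number of planted classes (<= `n_neurons`).
#' @param lambda_within,lambda_between Poisson synapse-count rates per
#'   ordered pair (`lambda_within > 0`, `lambda_between >= 0`).
#' @param jitter_sd_um Gaussian coordinate jitter applied to each neuron's
#'   nodes, um.
#' @param seed RNG seed; identical seeds give identical circuits.
#' @return An object of class `synthetic_circuit`: named `skeletons` list,
#'   integer `labels`, a [synapse_table()] `synapses`, the rates and the
#'   seed.
#' @export
make_circuit <- function(n_neurons = 40L, n_classes = 3L,
                         lambda_within = 8, lambda_between = 0.5,
                         jitter_sd_um = 2, seed = 1L) {
  if (n_classes > n_neurons) stop("`n_classes` cannot exceed `n_neurons`")
  if (lambda_within <= 0) stop("`lambda_within` must be positive")
  if (lambda_between < 0) stop("`lambda_between` must be >= 0")
  with_seed(seed, {
    labels <- rep(seq_len(n_classes), length.out = n_neurons)
    archetypes <- lapply(seq_len(n_classes), class_archetype,
                         n_classes = n_classes)
    skeletons <- lapply(seq_len(n_neurons), function(i) {
      skel <- archetypes[[labels[i]]]
      jit <- matrix(stats::rnorm(3L * nrow(skel), sd = jitter_sd_um * 1e3),
                    ncol = 3L)
      skel$x <- skel$x + jit[, 1L]
      skel$y <- skel$y + jit[, 2L]
      skel$z <- skel$z + jit[, 3L]
      skeleton(skel, validate = FALSE)
    })
    names(skeletons) <- as.character(seq_len(n_neurons))
    pairs <- expand.grid(pre = seq_len(n_neurons), post = seq_len(n_neurons))
    pairs <- pairs[pairs$pre != pairs$post, ]
    rate <- ifelse(labels[pairs$pre] == labels[pairs$post],
                   lambda_within, lambda_between)
    counts <- stats::rpois(nrow(pairs), rate)
    pre <- rep(pairs$pre, counts)
    post <- rep(pairs$post, counts)
    n_syn <- length(pre)
    roots <- t(vapply(skeletons, function(s) unlist(s[1L, c("x", "y", "z")]),
                      numeric(3L)))
    syn_pos <- (roots[pre, , drop = FALSE] + roots[post, , drop = FALSE]) / 2 +
      matrix(stats::rnorm(3L * n_syn, sd = 1e3), ncol = 3L)
    synapses <- synapse_table(data.frame(
      synapse_id = seq_len(n_syn), presyn = pre, postsyn = post,
      x_nm = syn_pos[, 1L], y_nm = syn_pos[, 2L], z_nm = syn_pos[, 3L]
    ))
    structure(
      list(skeletons = skeletons, labels = labels, synapses = synapses,
           lambda_within = lambda_within, lambda_between = lambda_between,
           rng_seed = as.integer(seed)),
      class = "synthetic_circuit"
    )
  })
}

#' @export
print.synthetic_circuit <- function(x, ...) {
  cat(sprintf("<synthetic_circuit> %d neurons, %d classes, %d synapses\n",
              length(x$skeletons), length(unique(x$labels)),
              nrow(x$synapses)))
  invisible(x)
}
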