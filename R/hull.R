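# Incremental 3D convex hull (quickhull-style point insertion), used for
# hull volumes. Written for modest point counts (skeleton nodes); exact on
# polytopes up to floating-point tolerance.

tetra_volume6 <- function(a, b, c, d) {
  det(rbind(b - a, c - a, d - a))
}

# Volume of the convex hull of an n x 3 point matrix; 0 when degenerate.
convex_hull_volume <- function(points) {
  pts <- unique(round(points, 12L))
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 4L) return(0)
  scale <- max(apply(pts, 2L, function(v) diff(range(v))))
  if (scale == 0) return(0)
  tol <- 1e-9 * scale^3  # tolerance on 6x signed tetra volumes

  # Initial simplex: two extreme points, then the point farthest from their
  # line, then the point farthest from their plane.
  i1 <- which.min(pts[, 1L])
  d2 <- rowSums(sweep(pts, 2L, pts[i1, ], "-")^2)
  i2 <- which.max(d2)
  ab <- pts[i2, ] - pts[i1, ]
  cr <- t(apply(sweep(pts, 2L, pts[i1, ], "-"), 1L,
                function(v) c(ab[2L] * v[3L] - ab[3L] * v[2L],
                              ab[3L] * v[1L] - ab[1L] * v[3L],
                              ab[1L] * v[2L] - ab[2L] * v[1L])))
  i3 <- which.max(rowSums(cr^2))
  vol6 <- apply(pts, 1L, function(p)
    tetra_volume6(pts[i1, ], pts[i2, ], pts[i3, ], p))
  i4 <- which.max(abs(vol6))
  if (abs(vol6[i4]) <= tol) return(0)  # all points coplanar

  interior <- colMeans(pts[c(i1, i2, i3, i4), , drop = FALSE])
  orient <- function(f) {
    # Ensure face normal points away from the interior reference point.
    if (tetra_volume6(pts[f[1L], ], pts[f[2L], ], pts[f[3L], ], interior) > 0)
      f[c(1L, 3L, 2L)] else f
  }
  faces <- list(orient(c(i1, i2, i3)), orient(c(i1, i2, i4)),
                orient(c(i1, i3, i4)), orient(c(i2, i3, i4)))

  above <- function(f, p) {
    # Positive when p is outside the oriented face plane.
    tetra_volume6(pts[f[1L], ], pts[f[2L], ], pts[f[3L], ], p)
  }

  for (p_idx in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    p <- pts[p_idx, ]
    vis <- vapply(faces, function(f) above(f, p) > tol, logical(1))
    if (!any(vis)) next
    # Horizon: directed edges of visible faces whose reverse lies on an
    # invisible face.
    vis_edges <- do.call(rbind, lapply(faces[vis], function(f)
      rbind(f[c(1L, 2L)], f[c(2L, 3L)], f[c(3L, 1L)])))
    keys <- paste(vis_edges[, 1L], vis_edges[, 2L])
    rev_keys <- paste(vis_edges[, 2L], vis_edges[, 1L])
    horizon <- vis_edges[!(keys %in% rev_keys), , drop = FALSE]
    faces <- faces[!vis]
    for (e in seq_len(nrow(horizon)))
      faces[[length(faces) + 1L]] <-
        orient(c(horizon[e, 1L], horizon[e, 2L], p_idx))
  }

  sum(vapply(faces, function(f)
    tetra_volume6(interior, pts[f[1L], ], pts[f[2L], ], pts[f[3L], ]),
    numeric(1))) / 6
}
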