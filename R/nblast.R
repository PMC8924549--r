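#' Construct dotprops from explicit points and tangents
#'
#' Low-level constructor used when points and tangents are already known
#' (e.g. analytic test objects); [make_dotprops()] is the usual entry point.
#'
#' @param points_um Numeric matrix (n x 3), um.
#' @param tangents Numeric matrix (n x 3) of unit vectors.
#' @return An object of class `dotprops`.
#' @export
dotprops <- function(points_um, tangents) {
  points_um <- as.matrix(points_um)
  tangents <- as.matrix(tangents)
  if (!all(dim(points_um) == dim(tangents)) || ncol(points_um) != 3L)
    stop("`points_um` and `tangents` must be matching n x 3 matrices")
  norms <- sqrt(rowSums(tangents^2))
  if (any(abs(norms - 1) > 1e-6)) stop("tangents must be unit vectors")
  structure(list(points_um = points_um, tangents = tangents),
            class = "dotprops")
}

#' Dotprops: resampled points with unit tangents
#'
#' The point-plus-tangent representation scored by NBLAST. The skeleton is
#' resampled to roughly `spacing_um` node spacing, positions are converted
#' to micrometers, and the tangent at each point is the dominant principal
#' axis of the point and its `k` nearest neighbors (sign-free).
#'
#' @param skel A [skeleton()] (coordinates in nm), or a numeric matrix of
#'   points in um (already resampled).
#' @param spacing_um Resampling spacing in um.
#' @param k Number of nearest neighbors used for the tangent fit.
#' @return An object of class `dotprops` with `points_um` (n x 3) and unit
#'   `tangents` (n x 3).
#' @export
make_dotprops <- function(skel, spacing_um = 1, k = 5L) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  if (inherits(skel, "skeleton")) {
    skel <- resample_skeleton(skel, spacing_um * 1000)
    pts <- skel_xyz(skel) / 1000
  } else {
    pts <- as.matrix(skel)
  }
  n <- nrow(pts)
  if (n < k + 1L)
    skel_error("skelemorph_too_small",
               sprintf("need at least k + 1 = %d points, got %d", k + 1L, n))
  d2 <- cross_dist2(pts, pts)
  tangents <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k + 1L)]  # the point and its k neighbors
    cv <- stats::cov(pts[nb, , drop = FALSE])
    ev <- eigen(cv, symmetric = TRUE)
    tangents[i, ] <- ev$vectors[, 1L]
  }
  structure(list(points_um = pts, tangents = tangents), class = "dotprops")
}

#' @export
print.dotprops <- function(x, ...) {
  cat(sprintf("<dotprops> %d points\n", nrow(x$points_um)))
  invisible(x)
}

#' NBLAST score functions
#'
#' Either the parametric form `f(d, adp) = adp * exp(-d / sigma_um)` —
#' rewarding close points with aligned tangents — or a matrix tabulated
#' over distance and absolute-dot-product bins, as published score matrices
#' are.
#'
#' @param sigma_um Distance decay constant, um.
#' @return An object of class `nblast_score_fn`.
#' @export
score_function <- function(sigma_um = 3) {
  if (sigma_um <= 0) stop("`sigma_um` must be positive")
  structure(list(type = "parametric", sigma_um = sigma_um),
            class = "nblast_score_fn")
}

#' @param scores Numeric matrix of scores, distance bins in rows and
#'   absolute-dot-product bins in columns.
#' @param dist_breaks_um Distance bin edges, length `nrow(scores) + 1`,
#'   starting at 0; the last edge may be `Inf`.
#' @param dot_breaks Dot-product bin edges in `[0, 1]`, length
#'   `ncol(scores) + 1`.
#' @rdname score_function
#' @export
score_function_table <- function(scores, dist_breaks_um, dot_breaks) {
  scores <- as.matrix(scores)
  if (length(dist_breaks_um) != nrow(scores) + 1L ||
      length(dot_breaks) != ncol(scores) + 1L)
    stop("bin edges must be one longer than the score matrix extent")
  if (dist_breaks_um[1L] != 0 || dot_breaks[1L] != 0 ||
      dot_breaks[length(dot_breaks)] != 1)
    stop("bins must cover [0, Inf) x [0, 1]")
  structure(list(type = "table", scores = scores,
                 dist_breaks_um = dist_breaks_um, dot_breaks = dot_breaks),
            class = "nblast_score_fn")
}

#' Read a tabulated score matrix from CSV
#'
#' Layout: the header row holds the upper dot-product bin edges, the first
#' column the upper distance bin edges (the lower edges are 0 and the
#' previous upper edge; `Inf` is allowed as the last distance edge).
#'
#' @param path CSV file path.
#' @return An `nblast_score_fn` of type `"table"`.
#' @export
read_score_function <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  dist_upper <- as.numeric(df[[1L]])
  scores <- as.matrix(df[, -1L, drop = FALSE])
  dot_upper <- as.numeric(colnames(scores))
  score_function_table(unname(scores), c(0, dist_upper), c(0, dot_upper))
}

score_eval <- function(fn, d_um, adp) {
  stopifnot(inherits(fn, "nblast_score_fn"))
  if (fn$type == "parametric") return(adp * exp(-d_um / fn$sigma_um))
  di <- findInterval(d_um, fn$dist_breaks_um, rightmost.closed = FALSE,
                     all.inside = TRUE)
  ai <- findInterval(adp, fn$dot_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  fn$scores[cbind(di, ai)]
}

#' Raw NBLAST score of a query against a target
#'
#' Sum over query points of the score function evaluated at the distance to
#' the nearest target point and the absolute dot product of the two unit
#' tangents there.
#'
#' @param query,target [make_dotprops()] objects.
#' @param fn A [score_function()].
#' @return Numeric scalar.
#' @export
nblast_raw <- function(query, target, fn = score_function()) {
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"))
  if (nrow(query$points_um) == 0L || nrow(target$points_um) == 0L)
    stop("dotprops must be nonempty")
  d2 <- cross_dist2(query$points_um, target$points_um)
  nn <- max.col(-d2, ties.method = "first")
  d <- sqrt(d2[cbind(seq_len(nrow(d2)), nn)])
  adp <- abs(rowSums(query$tangents * target$tangents[nn, , drop = FALSE]))
  adp <- pmin(adp, 1)
  sum(score_eval(fn, d, adp))
}

#' All-pairs NBLAST similarity matrix
#'
#' Normalizes every raw score by the query's self-score
#' (`normalized[q, t] = raw(q, t) / raw(q, q)`, so the diagonal is 1) and
#' symmetrizes by averaging the two directions. The associated
#' dissimilarity is `1 - symmetrized`, clipped at 0.
#'
#' @param dotprops_list Named list of [make_dotprops()] objects (>= 2).
#' @param fn A [score_function()].
#' @return An object of class `similarity_matrix` with `ids`, `raw`,
#'   `normalized` and `symmetrized` matrices.
#' @export
nblast_matrix <- function(dotprops_list, fn = score_function()) {
  n <- length(dotprops_list)
  if (n < 2L) stop("need at least 2 neurons")
  ids <- names(dotprops_list)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  raw <- matrix(0, n, n, dimnames = list(ids, ids))
  for (q in seq_len(n)) for (t in seq_len(n))
    raw[q, t] <- nblast_raw(dotprops_list[[q]], dotprops_list[[t]], fn)
  if (any(diag(raw) <= 0))
    skel_error("skelemorph_degenerate_neuron",
               "a neuron has non-positive self-score")
  normalized <- raw / diag(raw)
  symmetrized <- (normalized + t(normalized)) / 2
  structure(list(ids = ids, raw = raw, normalized = normalized,
                 symmetrized = symmetrized),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d neurons\n", length(x$ids)))
  invisible(x)
}

#' Dissimilarity matrix of an NBLAST similarity
#'
#' `pmax(0, 1 - symmetrized)` with a zero diagonal.
#'
#' @param sim A [nblast_matrix()] result.
#' @return Numeric distance matrix.
#' @export
nblast_distance <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  d <- 1 - sim$symmetrized
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Cluster neurons by NBLAST similarity
#'
#' Average-linkage agglomerative clustering on the NBLAST dissimilarity,
#' cut to a requested number of morphological types.
#'
#' @param sim A [nblast_matrix()] result.
#' @param n_clusters Number of clusters (<= number of neurons).
#' @return List with integer `labels` (named by neuron id) and the `hclust`
#'   dendrogram `tree`.
#' @export
nblast_cluster <- function(sim, n_clusters) {
  stopifnot(inherits(sim, "similarity_matrix"))
  n <- length(sim$ids)
  if (n_clusters > n) stop("`n_clusters` cannot exceed the number of neurons")
  tree <- stats::hclust(stats::as.dist(nblast_distance(sim)),
                        method = "average")
  labels <- stats::cutree(tree, k = n_clusters)
  names(labels) <- sim$ids
  list(labels = labels, tree = tree)
}

#' Export a similarity matrix as CSV
#'
#' Writes the symmetrized normalized scores with neuron ids as header row
#' and first column.
#'
#' @param sim A [nblast_matrix()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- data.frame(neuron = sim$ids, sim$symmetrized, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
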