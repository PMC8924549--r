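#' Synapse table
#'
#' One row per detected synapse: id, presynaptic neuron id, postsynaptic
#' neuron id and position in nm. Synapse detection itself happens upstream;
#' this module only consumes its CSV output.
#'
#' @param df Data frame with columns `synapse_id`, `presyn`, `postsyn`,
#'   `x_nm`, `y_nm`, `z_nm` (the longer names `presyn_neuron_id`,
#'   `postsyn_neuron_id` and `x`/`y`/`z` are accepted and normalized).
#' @return An object of class `synapse_table` (also a `data.frame`).
#' @export
synapse_table <- function(df) {
  aliases <- c(presyn_neuron_id = "presyn", postsyn_neuron_id = "postsyn",
               x = "x_nm", y = "y_nm", z = "z_nm")
  for (a in names(aliases))
    if (a %in% names(df) && !(aliases[[a]] %in% names(df)))
      names(df)[names(df) == a] <- aliases[[a]]
  required <- c("synapse_id", "presyn", "postsyn", "x_nm", "y_nm", "z_nm")
  if (!all(required %in% names(df)))
    stop_format(paste("synapse table needs columns:",
                      paste(required, collapse = ", ")))
  df <- as.data.frame(df)[required]
  if (any(df$presyn <= 0) || any(df$postsyn <= 0))
    stop_format("neuron ids must be positive")
  if (any(!is.finite(as.matrix(df[, c("x_nm", "y_nm", "z_nm")]))))
    stop_format("synapse coordinates must be finite")
  structure(df, class = c("synapse_table", "data.frame"))
}

#' Read / write a synapse table as CSV
#'
#' @param path CSV path with header
#'   `synapse_id,presyn,postsyn,x_nm,y_nm,z_nm`.
#' @param table A [synapse_table()].
#' @return `read_synapses` returns a [synapse_table()]; `write_synapses`
#'   returns `path` invisibly.
#' @export
read_synapses <- function(path) {
  synapse_table(utils::read.csv(path))
}

#' @rdname read_synapses
#' @export
write_synapses <- function(table, path) {
  stopifnot(inherits(table, "synapse_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Build a directed synapse-count connectivity matrix
#'
#' `counts[i, j]` is the number of synapses from neuron `i` onto neuron
#' `j`; autapses land on the diagonal. The synapse count is the
#' connectedness metric: more synapses, closer neurons. Rows whose pre- or
#' postsynaptic id is not in `ids` are dropped with a message.
#'
#' @param table A [synapse_table()].
#' @param ids Unique neuron ids ordering the matrix.
#' @return An integer matrix of class `connectivity_matrix` with `ids` as
#'   dimnames.
#' @export
build_connectivity <- function(table, ids) {
  stopifnot(inherits(table, "synapse_table"))
  if (length(ids) == 0L) stop("`ids` must be nonempty")
  if (anyDuplicated(ids)) stop("`ids` must be unique")
  ids <- as.character(ids)
  pre <- as.character(table$presyn)
  post <- as.character(table$postsyn)
  known <- pre %in% ids & post %in% ids
  if (any(!known))
    message(sprintf("dropping %d synapse rows with unknown neuron ids",
                    sum(!known)))
  counts <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (any(known)) {
    tab <- table(factor(pre[known], levels = ids),
                 factor(post[known], levels = ids))
    counts[] <- as.integer(tab)
  }
  structure(counts, class = c("connectivity_matrix", "matrix", "array"))
}

#' Connectivity distance
#'
#' Maps symmetrized synapse counts `s_ij = counts[i,j] + counts[j,i]` to a
#' distance in `(0, 1]` via `d_ij = 1 / (1 + s_ij)`, with a zero diagonal:
#' the more synapses connect two neurons, the closer they are.
#'
#' @param m A [build_connectivity()] matrix.
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
connectivity_distance <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  s <- unclass(m) + t(unclass(m))
  d <- 1 / (1 + s)
  diag(d) <- 0
  d
}

#' Cluster neurons by connectivity
#'
#' Average-linkage hierarchical clustering on the connectivity distance.
#'
#' @param m A [build_connectivity()] matrix.
#' @param n_clusters Number of communities to cut to.
#' @return List with integer `labels` (named by neuron id) and the `hclust`
#'   `tree`.
#' @export
connectivity_cluster <- function(m, n_clusters) {
  d <- connectivity_distance(m)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  if (n_clusters > nrow(m)) stop("`n_clusters` cannot exceed matrix size")
  labels <- stats::cutree(tree, k = n_clusters)
  names(labels) <- rownames(m)
  list(labels = labels, tree = tree)
}

#' Reorder a connectivity matrix by clustering
#'
#' Permutes rows and columns identically, either by the leaf order of a
#' dendrogram (`hclust`) or by grouping a label vector (stable within
#' groups), e.g. to reorder synaptic connectivity by morphological (NBLAST)
#' clusters.
#'
#' @param m A [build_connectivity()] matrix.
#' @param order_by An `hclust` tree over the same ids, or a vector of
#'   cluster labels named by neuron id.
#' @return List with the permuted `matrix` and the integer `permutation`
#'   applied.
#' @export
reorder_connectivity <- function(m, order_by) {
  stopifnot(inherits(m, "connectivity_matrix"))
  ids <- rownames(m)
  if (inherits(order_by, "hclust")) {
    perm <- order_by$order
    if (length(perm) != length(ids)) stop("dendrogram does not cover all ids")
  } else {
    if (is.null(names(order_by))) stop("labels must be named by neuron id")
    if (!all(ids %in% names(order_by))) stop("missing id in labels")
    perm <- order(order_by[ids])  # stable within groups
  }
  out <- unclass(m)[perm, perm, drop = FALSE]
  list(matrix = structure(out, class = class(m)), permutation = perm)
}

#' Association between morphological similarity and connectivity
#'
#' Spearman rank correlation, over unordered neuron pairs, between the
#' symmetrized NBLAST score and the symmetrized synapse count, with a
#' permutation p-value obtained by shuffling neuron identity in the
#' connectivity matrix.
#'
#' @param sim A [nblast_matrix()] result.
#' @param m A [build_connectivity()] matrix over the same neuron ids.
#' @param n_perm Number of identity permutations (>= 999 recommended).
#' @param seed RNG seed for the permutations.
#' @return List with `rho`, `p_value` and `n_pairs` (`rho` is `NA` and the
#'   p-value undefined when either vector is constant, e.g. all-zero
#'   counts).
#' @export
morphology_connectivity_association <- function(sim, m, n_perm = 999L,
                                                seed = 1L) {
  stopifnot(inherits(sim, "similarity_matrix"),
            inherits(m, "connectivity_matrix"))
  ids <- sim$ids
  if (!setequal(ids, rownames(m)))
    stop("similarity and connectivity must cover the same neuron ids")
  cm <- unclass(m)[ids, ids]
  s <- cm + t(cm)
  upper <- upper.tri(s)
  x <- sim$symmetrized[upper]
  y <- s[upper]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p_value = NA_real_, n_pairs = sum(upper)))
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(ids)
  exceed <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      sp <- s[p, p][upper]
      r <- stats::cor(x, sp, method = "spearman")
      if (abs(r) >= abs(rho)) count <- count + 1L
    }
    count
  })
  list(rho = rho, p_value = (1 + exceed) / (n_perm + 1),
       n_pairs = sum(upper))
}

#' Export a connectivity matrix as CSV
#'
#' Neuron ids as header row and first column.
#'
#' @param m A [build_connectivity()] matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  df <- data.frame(neuron = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix from CSV
#' @param path CSV written by [write_connectivity_csv()].
#' @return A `connectivity_matrix`.
#' @export
read_connectivity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ids, ids)
  structure(m, class = c("connectivity_matrix", "matrix", "array"))
}
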