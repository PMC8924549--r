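#' Segmentation chunk
#'
#' A chunk of a labeled segmentation volume: a 3D array of unsigned integer
#' object IDs (0 = background) with an anisotropic voxel size in nanometers
#' and the global voxel index of the chunk origin.
#'
#' Coordinate convention: voxel indices are 0-based and global; the physical
#' position of a voxel is `(global_index + 0.5) * spacing_nm`, i.e. voxel
#' centers, in nm.
#'
#' @param labels 3D array of non-negative integer object IDs.
#' @param spacing_nm Per-axis voxel size in nm, e.g. `c(5, 5, 45)`.
#' @param offset_vox Global 0-based voxel index of the `[1,1,1]` array corner.
#' @return An object of class `seg_chunk`.
#' @examples
#' lab <- array(0L, c(4, 4, 4)); lab[2:3, 2:3, 2:3] <- 1L
#' chunk <- seg_chunk(lab, spacing_nm = c(5, 5, 45))
#' @export
seg_chunk <- function(labels, spacing_nm, offset_vox = c(0L, 0L, 0L)) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  if (any(dim(labels) < 1L)) stop("all dimensions must be >= 1")
  if (any(labels < 0)) stop("object IDs must be non-negative")
  spacing_nm <- check_len3_positive(spacing_nm, "spacing_nm")
  if (length(offset_vox) != 3L) stop("`offset_vox` must have length 3")
  structure(
    list(labels = labels, spacing_nm = spacing_nm,
         offset_vox = as.integer(offset_vox)),
    class = "seg_chunk"
  )
}

#' @export
print.seg_chunk <- function(x, ...) {
  cat(sprintf("<seg_chunk> %s voxels, spacing %s nm, offset (%s)\n",
              paste(dim(x$labels), collapse = "x"),
              paste(x$spacing_nm, collapse = "x"),
              paste(x$offset_vox, collapse = ",")))
  invisible(x)
}

#' Bit-pack a single object's binary mask
#'
#' Extracts the occupancy mask of one object ID from a segmentation chunk and
#' packs it at 1 bit per voxel, an 8-fold reduction over a byte-per-voxel
#' mask. The payload layout is fixed: voxels are linearized x-fastest (array
#' order), and within each byte the first voxel occupies the least
#' significant bit (little-endian bit significance).
#'
#' @param chunk A [seg_chunk()].
#' @param object_id Positive object ID; 0 (background) is rejected.
#' @return An object of class `bitpacked_mask` with fields `dims`,
#'   `spacing_nm`, `offset_vox` and the raw `bits` payload of exactly
#'   `ceiling(prod(dims) / 8)` bytes.
#' @seealso [unpack_mask()], [extract_point_cloud()], [compute_dbf()]
#' @export
pack_mask <- function(chunk, object_id) {
  stopifnot(inherits(chunk, "seg_chunk"))
  if (length(object_id) != 1L || is.na(object_id) || object_id <= 0)
    stop("`object_id` must be a single positive integer (0 is background)")
  mask <- as.vector(chunk$labels == object_id)
  pad <- (-length(mask)) %% 8L
  bits <- packBits(c(mask, rep(FALSE, pad)), type = "raw")
  structure(
    list(dims = dim(chunk$labels), spacing_nm = chunk$spacing_nm,
         offset_vox = chunk$offset_vox, bits = bits),
    class = "bitpacked_mask"
  )
}

#' Unpack a bit-packed mask to a logical array
#'
#' Inverse of [pack_mask()]: `unpack_mask(pack_mask(chunk, id))` equals
#' `chunk$labels == id` elementwise.
#'
#' @param mask A `bitpacked_mask`.
#' @return Logical 3D array of dimensions `mask$dims`.
#' @export
unpack_mask <- function(mask) {
  stopifnot(inherits(mask, "bitpacked_mask"))
  v <- as.logical(rawToBits(mask$bits))[seq_len(prod(mask$dims))]
  array(v, dim = mask$dims)
}

#' @export
print.bitpacked_mask <- function(x, ...) {
  cat(sprintf("<bitpacked_mask> %s voxels, %d payload bytes, %d set\n",
              paste(x$dims, collapse = "x"), length(x$bits),
              mask_popcount(x)))
  invisible(x)
}

#' Number of set voxels in a bit-packed mask
#' @param mask A `bitpacked_mask`.
#' @return Integer count of foreground voxels.
#' @export
mask_popcount <- function(mask) {
  sum(as.integer(rawToBits(mask$bits)))
}

#' Point cloud of foreground voxels
#'
#' Foreground voxel coordinates of one object, optionally annotated with the
#' distance-from-boundary field (DBF). Points are kept in deterministic
#' lexicographic order of their global `(i, j, k)` voxel indices.
#'
#' @param points_vox Integer matrix (n x 3) of global 0-based voxel indices.
#' @param spacing_nm Per-axis voxel size in nm.
#' @param dbf_nm Optional numeric vector of per-point distances to the
#'   nearest background voxel center, in nm (all positive).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points_vox, spacing_nm, dbf_nm = NULL) {
  points_vox <- matrix(as.integer(points_vox), ncol = 3L)
  spacing_nm <- check_len3_positive(spacing_nm, "spacing_nm")
  if (!is.null(dbf_nm)) {
    if (length(dbf_nm) != nrow(points_vox))
      stop("`dbf_nm` must have one value per point")
    if (any(dbf_nm <= 0)) stop("all dbf values must be positive")
  }
  structure(
    list(points_vox = points_vox, spacing_nm = spacing_nm,
         dbf_nm = dbf_nm),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, dbf %s\n", nrow(x$points_vox),
              if (is.null(x$dbf_nm)) "unset" else "set"))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points_vox)

# Physical voxel-center positions (nm) of the points in a cloud.
point_positions_nm <- function(cloud) {
  sweep(cloud$points_vox + 0.5, 2L, cloud$spacing_nm, "*")
}

#' Extract the point cloud of a mask
#'
#' One point per set voxel, in global 0-based coordinates (the chunk offset
#' is applied), sorted lexicographically by `(i, j, k)`. The DBF is unset.
#'
#' @param mask A `bitpacked_mask`.
#' @return A [point_cloud()] (empty mask gives an empty cloud).
#' @export
extract_point_cloud <- function(mask) {
  arr <- unpack_mask(mask)
  w <- which(arr, arr.ind = TRUE)
  if (nrow(w) == 0L)
    return(point_cloud(matrix(integer(0), ncol = 3L), mask$spacing_nm))
  pts <- w - 1L
  pts <- pts[order(pts[, 1L], pts[, 2L], pts[, 3L]), , drop = FALSE]
  pts <- sweep(pts, 2L, mask$offset_vox, "+")
  point_cloud(pts, mask$spacing_nm)
}

# 1D squared distance transform (Felzenszwalb & Huttenlocher lower envelope)
# with anisotropic sample spacing `s`. `f` holds current squared distances
# (Inf for yet-unreached foreground samples).
dt1d_sq <- function(f, s) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(rep(Inf, n))
  x <- seq_len(n) * s
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 0L
  s_int <- -Inf
  for (q in fin) {
    repeat {
      if (k == 0L) break
      p <- v[k]
      s_int <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (s_int <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- if (k == 1L) -Inf else s_int
    z[k + 1L] <- Inf
  }
  out <- numeric(n)
  ki <- 1L
  for (q in seq_len(n)) {
    while (z[ki + 1L] < x[q]) ki <- ki + 1L
    p <- v[ki]
    out[q] <- (x[q] - x[p])^2 + f[p]
  }
  out
}

# Anisotropic squared Euclidean distance transform of a logical 3D array
# (distance from each TRUE voxel center to the nearest FALSE voxel center).
edt_sq <- function(fg, spacing_nm) {
  dims <- dim(fg)
  d <- array(ifelse(fg, Inf, 0), dim = dims)
  for (k in seq_len(dims[3L])) for (j in seq_len(dims[2L]))
    d[, j, k] <- dt1d_sq(d[, j, k], spacing_nm[1L])
  for (k in seq_len(dims[3L])) for (i in seq_len(dims[1L]))
    d[i, , k] <- dt1d_sq(d[i, , k], spacing_nm[2L])
  for (j in seq_len(dims[2L])) for (i in seq_len(dims[1L]))
    d[i, j, ] <- dt1d_sq(d[i, j, ], spacing_nm[3L])
  d
}

#' Compute the distance-from-boundary field (DBF)
#'
#' Annotates the mask's point cloud with the anisotropic Euclidean distance
#' from each foreground voxel center to the nearest background voxel center.
#' All space outside the mask's bounding box (padded by one voxel) counts as
#' background, so an object touching the chunk border still gets a finite,
#' positive DBF.
#'
#' @param mask A nonempty `bitpacked_mask`.
#' @return A [point_cloud()] with `dbf_nm` set, points in the same
#'   lexicographic order as [extract_point_cloud()].
#' @export
compute_dbf <- function(mask) {
  arr <- unpack_mask(mask)
  if (!any(arr)) stop_empty_object()
  dims <- dim(arr)
  padded <- array(FALSE, dims + 2L)
  padded[2:(dims[1L] + 1L), 2:(dims[2L] + 1L), 2:(dims[3L] + 1L)] <- arr
  d <- sqrt(edt_sq(padded, mask$spacing_nm))
  cloud <- extract_point_cloud(mask)
  local_idx <- sweep(cloud$points_vox, 2L, mask$offset_vox, "-") + 2L
  cloud$dbf_nm <- d[local_idx]
  cloud
}

#' Write / read a segmentation chunk as sparse plain text
#'
#' A simple language-agnostic text serialization of a [seg_chunk()]: three
#' header comment lines carrying `dims`, `spacing_nm` and `offset_vox`,
#' followed by one `i j k label` row (0-based local voxel indices) per
#' nonzero voxel, tab-separated.
#'
#' @param chunk A [seg_chunk()].
#' @param path File path.
#' @return `write_seg_tsv` returns `path` invisibly; `read_seg_tsv` returns
#'   the reconstructed [seg_chunk()].
#' @export
write_seg_tsv <- function(chunk, path) {
  stopifnot(inherits(chunk, "seg_chunk"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# dims", paste(dim(chunk$labels), collapse = " ")),
    paste("# spacing_nm", paste(format(chunk$spacing_nm, trim = TRUE), collapse = " ")),
    paste("# offset_vox", paste(chunk$offset_vox, collapse = " "))
  ), con)
  w <- which(chunk$labels != 0L, arr.ind = TRUE)
  if (nrow(w) > 0L) {
    df <- data.frame(w - 1L, label = chunk$labels[w])
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_seg_tsv
#' @export
read_seg_tsv <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  get_field <- function(key, n = 3L) {
    row <- header[startsWith(header, paste0("# ", key))]
    if (length(row) != 1L) stop_format(sprintf("missing '%s' header", key))
    as.numeric(strsplit(sub(paste0("# ", key, " "), "", row), "\\s+")[[1L]])
  }
  dims <- as.integer(get_field("dims"))
  spacing <- get_field("spacing_nm")
  offset <- as.integer(get_field("offset_vox"))
  labels <- array(0L, dims)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) > 0L) {
    m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
    if (ncol(m) != 4L || anyNA(m)) stop_format("malformed voxel row")
    labels[m[, 1:3, drop = FALSE] + 1L] <- as.integer(m[, 4L])
  }
  seg_chunk(labels, spacing, offset)
}
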