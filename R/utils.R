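# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes with tryCatch().
skel_error <- function(class, msg) {
  stop(structure(
    class = c(class, "skelemorph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_empty_object <- function() {
  skel_error("skelemorph_empty_object", "object has no foreground voxels")
}

stop_format <- function(msg) skel_error("skelemorph_format_error", msg)

# Squared Euclidean cross-distances between rows of A (n x d) and B (m x d).
cross_dist2 <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_len3_positive <- function(x, name) {
  if (length(x) != 3L || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be 3 positive finite values", name))
  as.numeric(x)
}
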