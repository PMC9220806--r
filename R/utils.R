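# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Coerce an n x 3 coordinate input (matrix or data.frame) to a numeric matrix.
as_coords <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  x
}

# Squared Euclidean distances between rows of a (n x 3) and b (m x 3): n x m.
cross_dist2 <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Minimum distance from each row of `pts` to any row of `ref`, via kd-tree.
min_dist_to <- function(pts, ref) {
  pts <- as_coords(pts); ref <- as_coords(ref)
  as.numeric(FNN::get.knnx(ref, pts, k = 1L)$nn.dist)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
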