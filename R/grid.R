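#' Density grid objects
#'
#' A `density_grid` is the package's container for a 3D cryoEM scalar field:
#' a numeric array of voxel values in a single canonical axis order
#' (array index 1 = x, 2 = y, 3 = z), the voxel size per axis in Angstrom,
#' the world-coordinate origin of the grid corner in Angstrom, and cached
#' map statistics (mean and sigma, the standard deviation over all voxels).
#' Sigma is the unit used for threshold bracketing and half-map filtering.
#'
#' The world coordinate of the *center* of voxel `(i, j, k)` (1-based) is
#' `origin + (i - 1, j - 1, k - 1) * voxel_size`.
#'
#' @param values 3D numeric array of voxel values.
#' @param voxel_size length-3 positive numeric, Angstrom per voxel along x,y,z.
#' @param origin length-3 numeric, Angstrom offset of the first voxel center.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(values, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(voxel_size <= 0)) stop("all voxel_size components must be > 0")
  storage.mode(values) <- "double"
  g <- structure(list(
    values = values,
    voxel_size = voxel_size,
    origin = origin,
    mean = mean(values),
    sigma = stats::sd(as.vector(values))
  ), class = "density_grid")
  if (length(values) == 1L) g$sigma <- 0
  g
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_grid %d x %d x %d, voxel %.3g/%.3g/%.3g A, origin (%.3g, %.3g, %.3g) A\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  mean %.4g  sigma %.4g  range [%.4g, %.4g]\n",
              x$mean, x$sigma, min(x$values), max(x$values)))
  invisible(x)
}

is_density_grid <- function(x) inherits(x, "density_grid")

check_grid <- function(g, arg = "grid") {
  if (!is_density_grid(g)) stop(sprintf("%s must be a density_grid", arg))
  invisible(g)
}

check_congruent <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$voxel_size - b$voxel_size)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-4)
    stop("grids are not congruent (shape, voxel size and origin must match)")
  invisible(TRUE)
}

#' Convert voxel indices to world coordinates and back
#'
#' `voxel_to_world` maps 1-based voxel indices to Angstrom coordinates of the
#' voxel centers; `world_to_voxel` is its (real-valued) inverse.
#'
#' @param grid a `density_grid`.
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @param xyz n x 3 matrix of Angstrom coordinates.
#' @return n x 3 numeric matrix.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- as_coords(ijk)
  sweep(sweep(ijk - 1, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- as_coords(xyz)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$voxel_size, "/") + 1
}

# Coordinates (voxel centers) of every voxel above `threshold`, plus values.
above_threshold_voxels <- function(grid, threshold) {
  idx <- which(grid$values > threshold)
  d <- dim(grid$values)
  ijk <- arrayInd(idx, d)
  list(coords = voxel_to_world(grid, ijk),
       values = grid$values[idx],
       index = idx)
}

# Trilinear interpolation of grid values at world coordinates (n x 3).
# Points outside the grid evaluate to 0.
interp_density <- function(grid, xyz) {
  v <- grid$values
  d <- dim(v)
  f <- world_to_voxel(grid, xyz)
  i0 <- floor(f)
  t <- f - i0
  out <- numeric(nrow(f))
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
        i0[, 1] <= d[1] - 1 & i0[, 2] <= d[2] - 1 & i0[, 3] <= d[3] - 1
  if (any(ok)) {
    i <- i0[ok, 1]; j <- i0[ok, 2]; k <- i0[ok, 3]
    tx <- t[ok, 1]; ty <- t[ok, 2]; tz <- t[ok, 3]
    at <- function(di, dj, dk) v[cbind(i + di, j + dj, k + dk)]
    out[ok] <-
      at(0,0,0) * (1-tx)*(1-ty)*(1-tz) + at(1,0,0) * tx*(1-ty)*(1-tz) +
      at(0,1,0) * (1-tx)*ty*(1-tz)     + at(0,0,1) * (1-tx)*(1-ty)*tz +
      at(1,1,0) * tx*ty*(1-tz)         + at(1,0,1) * tx*(1-ty)*tz +
      at(0,1,1) * (1-tx)*ty*tz         + at(1,1,1) * tx*ty*tz
  }
  # clamp exact upper-boundary points to nearest voxel instead of dropping them
  edge <- !ok & f[, 1] >= 1 & f[, 2] >= 1 & f[, 3] >= 1 &
          f[, 1] <= d[1] & f[, 2] <= d[2] & f[, 3] <= d[3]
  if (any(edge)) {
    r <- pmin(pmax(round(f[edge, , drop = FALSE]), 1), matrix(d, sum(edge), 3, byrow = TRUE))
    out[edge] <- v[r]
  }
  out
}
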