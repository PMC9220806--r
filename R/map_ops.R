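#' Low-pass filter a density map
#'
#' Applies a Gaussian low-pass filter in Fourier space. The transfer function
#' is `H(s) = exp(-(resolution * s)^2)` with `s` the spatial frequency in
#' 1/Angstrom, i.e. the real-space kernel is a Gaussian of standard deviation
#' `resolution / (pi * sqrt(2))` -- the same width convention the synthetic
#' map simulator uses. `H(0) = 1`, so the map mean is preserved exactly, and
#' `H(s) <= 1` everywhere, so total spectral power never increases. At the
#' nominal cutoff `s = 1/resolution` amplitudes are attenuated to
#' `exp(-1) ~ 0.37`.
#'
#' The pipeline's map-filtration step defaults to 4.5 Angstrom
#' (see [default_lowpass_resolution]).
#'
#' @param grid a [density_grid].
#' @param resolution low-pass resolution in Angstrom; must exceed twice the
#'   largest voxel dimension (Nyquist).
#' @return A filtered [density_grid] of identical shape.
#' @export
lowpass_filter <- function(grid, resolution = default_lowpass_resolution) {
  check_grid(grid)
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution <= 2 * max(grid$voxel_size))
    stop(sprintf("resolution (%.3g A) must exceed the Nyquist limit 2*max(voxel_size) = %.3g A",
                 resolution, 2 * max(grid$voxel_size)))
  d <- dim(grid$values)
  freq_axis <- function(n, step) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
    if (n == 1L) k <- 0
    k / (n * step)
  }
  fx <- freq_axis(d[1], grid$voxel_size[1])
  fy <- freq_axis(d[2], grid$voxel_size[2])
  fz <- freq_axis(d[3], grid$voxel_size[3])
  s2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  H <- exp(-(resolution^2) * s2)
  filt <- Re(stats::fft(stats::fft(grid$values) * H, inverse = TRUE)) / prod(d)
  density_grid(filt, voxel_size = grid$voxel_size, origin = grid$origin)
}

#' Default low-pass resolution (Angstrom) for the map-filtration step
#' @export
default_lowpass_resolution <- 4.5

#' Zero out density near a model
#'
#' Sets to zero every voxel whose center lies within `radius` of any atom in
#' `atom_coords`; all other voxels are unchanged. Membership is decided by
#' voxel-center distance, so the operation is idempotent. A radius of 0
#' disables masking.
#'
#' @param grid a [density_grid].
#' @param atom_coords n x 3 matrix of atom positions in Angstrom.
#' @param radius masking radius in Angstrom (>= 0).
#' @return A masked [density_grid].
#' @export
mask_near_model <- function(grid, atom_coords, radius) {
  check_grid(grid)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("radius must be a single non-negative number")
  if (is.null(atom_coords) || NROW(atom_coords) == 0L) {
    warning("empty atom list: returning grid unchanged")
    return(grid)
  }
  atom_coords <- as_coords(atom_coords)
  v <- grid$values
  if (radius > 0) {
    d <- dim(v)
    r_vox <- ceiling(radius / grid$voxel_size)
    for (a in seq_len(nrow(atom_coords))) {
      p <- atom_coords[a, ]
      c_vox <- (p - grid$origin) / grid$voxel_size + 1
      lo <- pmax(floor(c_vox - r_vox), 1)
      hi <- pmin(ceiling(c_vox + r_vox), d)
      if (any(lo > hi)) next
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      dx2 <- (grid$origin[1] + (ii - 1) * grid$voxel_size[1] - p[1])^2
      dy2 <- (grid$origin[2] + (jj - 1) * grid$voxel_size[2] - p[2])^2
      dz2 <- (grid$origin[3] + (kk - 1) * grid$voxel_size[3] - p[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      sub <- v[ii, jj, kk, drop = FALSE]
      sub[d2 <= radius^2] <- 0
      v[ii, jj, kk] <- sub
    }
  }
  density_grid(v, voxel_size = grid$voxel_size, origin = grid$origin)
}

#' Half-map consistency mask
#'
#' Flags voxels where two half-maps agree. The absolute half-map difference
#' is expressed in units of the full map's sigma (by default the standard
#' deviation of `(half1 + half2)/2` over all voxels); voxels whose difference
#' is below `half_thresh` sigma are kept. The result is symmetric in the two
#' half-map arguments.
#'
#' @param half1,half2 congruent [density_grid] half-maps.
#' @param half_thresh threshold difference in map-sigma units; default 0.5.
#' @param sigma optional explicit sigma (map units); when the full map is at
#'   hand, pass its sigma directly.
#' @return A logical 3D array (`TRUE` = keep) congruent with the half-maps.
#' @export
halfmap_consistency <- function(half1, half2, half_thresh = default_half_thresh,
                                sigma = NULL) {
  check_grid(half1, "half1"); check_grid(half2, "half2")
  check_congruent(half1, half2)
  if (is.null(sigma)) sigma <- stats::sd(as.vector((half1$values + half2$values) / 2))
  diff <- abs(half1$values - half2$values)
  if (sigma <= 0) return(array(diff == 0, dim = dim(diff)))
  diff / sigma < half_thresh
}

#' Default half-map difference threshold (map-sigma units)
#' @export
default_half_thresh <- 0.5
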