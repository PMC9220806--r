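#' Synthetic ground-truth systems
#'
#' The fixtures module builds fully known test systems: an ordered Calpha
#' trace, a simulated density map at a stated resolution, a pair of noisy
#' half-maps, and optionally planted non-protein blobs (a ligand, waters, and
#' a half-map-inconsistent artifact). Every generator is deterministic under
#' its seed, and the planted ground truth is kept on the returned object so
#' downstream recovery tests can score against it.
#'
#' @name fixtures
NULL

# exact-geometry helix: consecutive Calpha spacing 3.80 A, rise 1.5 A/residue,
# 100 degree turn (ideal alpha helix); radius solved from the spacing.
helix_points <- function(n, rise = 1.5, twist_deg = 100) {
  twist <- twist_deg * pi / 180
  radius <- sqrt(3.8^2 - rise^2) / (2 * sin(twist / 2))
  i <- seq_len(n) - 1
  cbind(radius * cos(i * twist), radius * sin(i * twist), i * rise)
}

strand_points <- function(n, rise = 3.3) {
  lat <- sqrt(3.8^2 - rise^2) / 2
  i <- seq_len(n) - 1
  cbind(i * rise, lat * (-1)^i, rep(0, n))
}

# resample a polyline at exact 3.8 A chord spacing (used for turns)
resample_chain <- function(pts, spacing = 3.8, n_out) {
  # densify, then walk picking points at exact chord distance `spacing`
  seg <- diff(pts)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  total <- cum[length(cum)]
  at <- function(s) { # arc-length parameterized point
    j <- findInterval(s, cum, rightmost.closed = TRUE)
    j <- min(max(j, 1L), nrow(pts) - 1L)
    f <- (s - cum[j]) / max(lens[j], 1e-12)
    pts[j, ] + f * (pts[j + 1, ] - pts[j, ])
  }
  out <- matrix(NA_real_, n_out, 3)
  out[1, ] <- pts[1, ]
  s <- 0
  for (k in 2:n_out) {
    # bisection on arc length for exact chord distance
    lo <- s; hi <- total
    pk <- out[k - 1, ]
    f_hi <- sqrt(sum((at(hi) - pk)^2))
    if (f_hi < spacing) stop("generation error: chain too short to resample")
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (sqrt(sum((at(mid) - pk)^2)) < spacing) lo <- mid else hi <- mid
    }
    s <- hi
    out[k, ] <- at(s)
  }
  out
}

#' Generate an ordered Calpha trace
#'
#' Consecutive points are 3.8 +/- 0.01 Angstrom apart and no two
#' non-consecutive points come closer than 3.0 Angstrom. Motifs: `helix`
#' (ideal alpha helix, 1.5 A rise per residue), `strand` (extended zig-zag),
#' `helix-turn-helix` (two antiparallel helices joined by an arc), and
#' `random-walk` (self-avoiding walk with persistence).
#'
#' @param n_res number of residues (>= 3).
#' @param motif one of `"helix"`, `"strand"`, `"helix-turn-helix"`,
#'   `"random-walk"`.
#' @param seed RNG seed (only the random walk consumes randomness).
#' @return n_res x 3 matrix of Calpha coordinates (Angstrom).
#' @export
make_ca_trace <- function(n_res, motif = c("helix", "strand", "helix-turn-helix",
                                           "random-walk"), seed = 0) {
  if (n_res < 3) stop("n_res must be >= 3")
  motif <- match.arg(motif)
  pts <- switch(motif,
    "helix" = helix_points(n_res),
    "strand" = strand_points(n_res),
    "helix-turn-helix" = {
      # centerline: up along z, arc over the top, back down offset in x; the
      # wobble makes ~2.2 A of axial advance per 3.8 A chord, so each arm
      # gets ~1.2 * n_res/2 Angstrom of axial extent plus slack
      sep <- 10
      top <- max(9, 1.2 * n_res / 2)
      arc_t <- seq(0, pi, length.out = 24)
      arc <- cbind(sep / 2 - (sep / 2) * cos(arc_t), 0, top + (sep / 2) * sin(arc_t))
      center <- rbind(cbind(0, 0, seq(0, top, by = 1.5)),
                      arc[-1, , drop = FALSE],
                      cbind(sep, 0, seq(top - 1.5, -3.8 * n_res, by = -1.5)))
      # wind a small helix around the centerline by adding lateral wobble
      tt <- seq_len(nrow(center))
      wob <- cbind(1.4 * cos(tt * 1.7), 1.4 * sin(tt * 1.7), 0)
      curve <- center + wob
      out <- resample_chain(curve, 3.8, n_res)
      check_trace(out)
      out
    },
    "random-walk" = with_seed(seed, random_walk_trace(n_res)))
  check_trace(pts)
  pts
}

check_trace <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  if (any(abs(d - 3.8) > 0.01))
    stop("generation error: consecutive spacing outside 3.8 +/- 0.01 A")
  n <- nrow(pts)
  if (n > 2) {
    dd <- as.matrix(stats::dist(pts))
    dd[cbind(1:n, 1:n)] <- Inf
    dd[cbind(1:(n - 1), 2:n)] <- Inf
    dd[cbind(2:n, 1:(n - 1))] <- Inf
    if (min(dd) < 3.0)
      stop("generation error: non-consecutive contact closer than 3.0 A")
  }
  invisible(pts)
}

random_walk_trace <- function(n_res, max_restarts = 50L) {
  for (r in seq_len(max_restarts)) {
    pts <- matrix(NA_real_, n_res, 3)
    pts[1, ] <- c(0, 0, 0)
    dir <- c(1, 0, 0)
    ok <- TRUE
    for (i in 2:n_res) {
      placed <- FALSE
      for (try in 1:40) {
        prop <- dir + stats::rnorm(3, sd = 0.45)   # persistent direction
        prop <- prop / sqrt(sum(prop^2))
        cand <- pts[i - 1, ] + 3.8 * prop
        if (i <= 3 || min(sqrt(colSums((t(pts[1:(i - 2), , drop = FALSE]) - cand)^2))) >= 3.2) {
          pts[i, ] <- cand; dir <- prop; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  stop("generation error: self-avoiding walk failed after bounded retries")
}

# kernel width convention: sd = resolution / (pi * sqrt(2))
resolution_sigma <- function(resolution) resolution / (pi * sqrt(2))

#' Simulate a density map from weighted points
#'
#' Each point contributes an isotropic 3D Gaussian of standard deviation
#' `resolution / (pi * sqrt(2))` and integrated amplitude proportional to its
#' weight (kernel peak height = weight). The grid extends at least `pad`
#' Angstrom beyond the coordinate extent.
#'
#' @param coords n x 3 matrix of point positions (Angstrom).
#' @param resolution nominal resolution in Angstrom (>= 2 * voxel_size).
#' @param voxel_size voxel edge in Angstrom (isotropic).
#' @param weights per-point kernel amplitudes (default 1).
#' @param pad padding beyond the coordinate extent, Angstrom.
#' @return A [density_grid].
#' @export
simulate_map <- function(coords, resolution = 4, voxel_size = 1, weights = NULL,
                         pad = 5) {
  coords <- as_coords(coords)
  if (nrow(coords) == 0L) stop("empty coordinate set")
  if (resolution < 2 * voxel_size) stop("resolution must be >= 2 * voxel_size")
  weights <- weights %||% rep(1, nrow(coords))
  sig <- resolution_sigma(resolution)
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  d <- pmax(ceiling((hi - lo) / voxel_size) + 1L, 2L)
  v <- array(0, dim = d)
  cutoff <- 4 * sig
  for (a in seq_len(nrow(coords))) {
    p <- coords[a, ]
    c_vox <- (p - lo) / voxel_size + 1
    lo_i <- pmax(floor(c_vox - cutoff / voxel_size), 1)
    hi_i <- pmin(ceiling(c_vox + cutoff / voxel_size), d)
    ii <- lo_i[1]:hi_i[1]; jj <- lo_i[2]:hi_i[2]; kk <- lo_i[3]:hi_i[3]
    gx <- exp(-((lo[1] + (ii - 1) * voxel_size - p[1])^2) / (2 * sig^2))
    gy <- exp(-((lo[2] + (jj - 1) * voxel_size - p[2])^2) / (2 * sig^2))
    gz <- exp(-((lo[3] + (kk - 1) * voxel_size - p[3])^2) / (2 * sig^2))
    v[ii, jj, kk] <- v[ii, jj, kk] + weights[a] * outer(outer(gx, gy), gz)
  }
  density_grid(v, voxel_size = rep(voxel_size, 3), origin = lo)
}

#' Simulate a pair of noisy half-maps
#'
#' Returns `map + noise1` and `map + noise2` with independent zero-mean
#' Gaussian voxel noise of standard deviation `noise_sigma` (map units).
#'
#' @param map a [density_grid].
#' @param noise_sigma noise standard deviation in map units (>= 0).
#' @param seed RNG seed.
#' @return A list with elements `half1` and `half2`.
#' @export
simulate_half_maps <- function(map, noise_sigma, seed = 0) {
  check_grid(map, "map")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  d <- dim(map$values)
  with_seed(seed, {
    n1 <- array(stats::rnorm(prod(d), sd = noise_sigma), dim = d)
    n2 <- array(stats::rnorm(prod(d), sd = noise_sigma), dim = d)
    list(half1 = density_grid(map$values + n1, map$voxel_size, map$origin),
         half2 = density_grid(map$values + n2, map$voxel_size, map$origin))
  })
}

#' Build a complete synthetic ground-truth system
#'
#' Convenience wrapper: trace, sequence, simulated map and half-maps in one
#' object. When a sequence is given, kernel weights are scaled by per-residue
#' heavy-atom counts (relative to alanine) so that bulky residues sit in
#' heavier density.
#'
#' @param n_res residue count.
#' @param motif trace motif, see [make_ca_trace()].
#' @param resolution simulated resolution, Angstrom.
#' @param voxel_size voxel edge, Angstrom.
#' @param sequence optional 1-letter sequence of length `n_res`.
#' @param noise_sigma half-map noise level (map units).
#' @param seed RNG seed.
#' @return A list of class `ground_truth_system` with fields `ca_coords`,
#'   `sequence`, `map`, `half1`, `half2`, `ligand_coords`, `water_coords`,
#'   `blob_coords`, `rng_seed`.
#' @export
make_ground_truth <- function(n_res, motif = "helix", resolution = 4,
                              voxel_size = 1, sequence = NULL,
                              noise_sigma = 0.02, seed = 0) {
  ca <- make_ca_trace(n_res, motif, seed = seed)
  if (!is.null(sequence)) {
    if (nchar(sequence) != n_res) stop("sequence length must equal n_res")
    w <- AA_HEAVY[strsplit(sequence, "")[[1]]] / AA_HEAVY[["A"]]
  } else w <- rep(1, n_res)
  map <- simulate_map(ca, resolution, voxel_size, weights = w)
  halves <- simulate_half_maps(map, noise_sigma, seed = seed + 1L)
  structure(list(ca_coords = ca, sequence = sequence, map = map,
                 half1 = halves$half1, half2 = halves$half2,
                 ligand_coords = NULL, water_coords = NULL, blob_coords = NULL,
                 resolution = resolution, noise_sigma = noise_sigma,
                 rng_seed = seed), class = "ground_truth_system")
}

#' Plant non-protein density into a ground-truth system
#'
#' Adds (a) one connected ligand blob within 5 Angstrom of the protein
#' surface -- `elongated` (12 points along a line, 1.4 A spacing) or
#' `globular` (points in a compact ball); (b) `n_waters` isolated single
#' points, each 2.5 Angstrom or more from everything else yet within 5
#' Angstrom of the protein so the model-distance filter retains them; and
#' optionally (c) one extra "inconsistent" blob present in `half1` only (the
#' full map carries it at half amplitude, consistent with the full map being
#' the half-map average, so the half-map difference at the blob is large).
#' The map and half-maps are rebuilt; planted coordinates are recorded on the
#' returned system.
#'
#' @param system a `ground_truth_system`.
#' @param ligand_shape `"elongated"`, `"globular"`, or `"none"`.
#' @param n_waters number of planted waters.
#' @param inconsistent_blob logical; plant a half1-only artifact blob.
#' @param amplitude kernel amplitude for planted points (map units, relative
#'   to a protein residue's weight of 1).
#' @param seed RNG seed for placement jitter.
#' @return The updated `ground_truth_system`.
#' @export
plant_nonprotein <- function(system, ligand_shape = c("elongated", "globular", "none"),
                             n_waters = 0, inconsistent_blob = FALSE,
                             amplitude = 1, seed = 0) {
  if (!inherits(system, "ground_truth_system")) stop("system must be a ground_truth_system")
  ligand_shape <- match.arg(ligand_shape)
  ca <- system$ca_coords
  if (ligand_shape == "none" && n_waters == 0 && !inconsistent_blob) return(system)

  # candidate surface anchors: extreme-x and extreme-y residues
  used <- ca
  place_at_band <- function(anchor_dir, along, n_pts, spacing, lo_d = 2.8, hi_d = 5.0,
                            min_sep = 2.5) {
    # try anchors down the protein surface (sorted by projection on
    # anchor_dir) and offsets outward until every point of the group sits in
    # the [lo_d, hi_d] band from the protein and >= min_sep from everything
    proj <- as.numeric(ca %*% anchor_dir)
    anchors <- ca[order(-proj)[seq_len(min(nrow(ca), 15L))], , drop = FALSE]
    offs <- seq_len(n_pts) - (n_pts + 1) / 2
    for (a in seq_len(nrow(anchors))) for (off in seq(3.0, 7, by = 0.25)) {
      base <- anchors[a, ] + off * anchor_dir
      pts <- sweep(outer(offs, along) * spacing, 2, base, "+")
      d_prot <- min_dist_to(pts, ca)
      if (any(d_prot < lo_d) || any(d_prot > hi_d)) next
      if (min(min_dist_to(pts, used)) < min_sep) next
      return(pts)
    }
    NULL
  }

  lig <- NULL
  if (ligand_shape != "none") {
    n_lp <- 12L
    dir_out <- c(1, 0, 0)
    along <- pick_tangent(ca, dir_out)
    if (ligand_shape == "elongated") {
      lig <- place_at_band(dir_out, along, n_lp, spacing = 1.4)
    } else {
      lig <- with_seed(seed, {
        base <- NULL
        for (off in seq(3.2, 12, by = 0.25)) {
          cand <- find_surface_anchor(ca, dir_out) + off * dir_out
          jit <- matrix(stats::rnorm(n_lp * 3, sd = 0.9), n_lp, 3)
          pts <- sweep(jit, 2, cand, "+")
          d_prot <- min_dist_to(pts, ca)
          if (all(d_prot >= 2.8) && all(d_prot <= 5.0)) { base <- pts; break }
        }
        base
      })
    }
    if (is.null(lig)) stop("generation error: no ligand placement found")
    used <- rbind(used, lig)
  }

  waters <- NULL
  if (n_waters > 0) {
    waters <- matrix(NA_real_, 0, 3)
    # spread anchors along the chain on the -x side
    anchors <- ca[round(seq(2, nrow(ca) - 1, length.out = max(n_waters, 2))), , drop = FALSE]
    dirs <- list(c(-1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                 c(-0.7, -0.7, 0), c(-0.7, 0.7, 0), c(0, 0, 1), c(0, 0, -1))
    for (w in seq_len(n_waters)) {
      placed <- FALSE
      for (dir in dirs) { for (off in seq(3.0, 4.6, by = 0.2)) {
        cand <- anchors[w, ] + off * dir
        d_prot <- min_dist_to(matrix(cand, 1), ca)
        if (d_prot < 2.9 || d_prot > 4.8) next
        if (min(min_dist_to(matrix(cand, 1), used)) < 2.5) next
        if (nrow(waters) > 0 && min(min_dist_to(matrix(cand, 1), waters)) < 5.0) next
        waters <- rbind(waters, cand); placed <- TRUE; break
      }; if (placed) break }
      if (!placed) stop("generation error: no water placement found")
    }
    used <- rbind(used, waters)
  }

  blob <- NULL
  if (inconsistent_blob) {
    along <- c(0, 0, 1)
    blob <- place_at_band(c(0, 1, 0), along, 4L, spacing = 1.4)
    if (is.null(blob)) stop("generation error: no blob placement found")
  }

  # rebuild map over the union footprint
  if (!is.null(system$sequence)) {
    w_prot <- AA_HEAVY[strsplit(system$sequence, "")[[1]]] / AA_HEAVY[["A"]]
  } else w_prot <- rep(1, nrow(ca))
  all_pts <- rbind(ca, lig, waters, blob)
  all_w <- c(w_prot,
             if (!is.null(lig)) rep(amplitude, nrow(lig)),
             if (!is.null(waters)) rep(amplitude, nrow(waters)),
             if (!is.null(blob)) rep(amplitude / 2, nrow(blob)))  # half in full map
  vox <- system$map$voxel_size[1]
  map <- simulate_map(all_pts, system$resolution, vox, weights = all_w)
  halves <- simulate_half_maps(map, system$noise_sigma, seed = system$rng_seed + 1L)
  if (!is.null(blob)) {
    # blob lives in half1 only, at full amplitude there (mean across halves
    # equals the full map's half-amplitude blob)
    extra <- simulate_map_onto(halves$half1, blob, system$resolution,
                               weights = rep(amplitude, nrow(blob)))
    halves$half1 <- extra
  }
  system$map <- map
  system$half1 <- halves$half1
  system$half2 <- halves$half2
  system$ligand_coords <- lig
  system$water_coords <- waters
  system$blob_coords <- blob
  system
}

# add Gaussian kernels for `coords` onto an existing grid (same lattice)
simulate_map_onto <- function(grid, coords, resolution, weights = NULL) {
  coords <- as_coords(coords)
  weights <- weights %||% rep(1, nrow(coords))
  sig <- resolution_sigma(resolution)
  v <- grid$values
  d <- dim(v)
  cutoff <- 4 * sig
  for (a in seq_len(nrow(coords))) {
    p <- coords[a, ]
    c_vox <- (p - grid$origin) / grid$voxel_size + 1
    lo_i <- pmax(floor(c_vox - cutoff / grid$voxel_size), 1)
    hi_i <- pmin(ceiling(c_vox + cutoff / grid$voxel_size), d)
    if (any(lo_i > hi_i)) next
    ii <- lo_i[1]:hi_i[1]; jj <- lo_i[2]:hi_i[2]; kk <- lo_i[3]:hi_i[3]
    gx <- exp(-((grid$origin[1] + (ii - 1) * grid$voxel_size[1] - p[1])^2) / (2 * sig^2))
    gy <- exp(-((grid$origin[2] + (jj - 1) * grid$voxel_size[2] - p[2])^2) / (2 * sig^2))
    gz <- exp(-((grid$origin[3] + (kk - 1) * grid$voxel_size[3] - p[3])^2) / (2 * sig^2))
    v[ii, jj, kk] <- v[ii, jj, kk] + weights[a] * outer(outer(gx, gy), gz)
  }
  density_grid(v, grid$voxel_size, grid$origin)
}

find_surface_anchor <- function(ca, dir) {
  proj <- ca %*% dir
  ca[which.max(proj), ]
}

pick_tangent <- function(ca, dir) {
  # a unit vector orthogonal to `dir`, roughly along the chain's long axis
  cc <- sweep(ca, 2, colMeans(ca))
  v <- svd(cc, nu = 0, nv = 1)$v[, 1]
  v <- v - sum(v * dir) * dir
  n <- sqrt(sum(v^2))
  if (n < 1e-6) v <- c(0, 0, 1) - dir[3] * dir else v <- v / n
  v / sqrt(sum(v^2))
}

#' Write a ground-truth manifest
#'
#' Records seeds and planted coordinates as plain-text key=value lines so a
#' run can be reproduced and scored later.
#'
#' @param system a `ground_truth_system`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(system, path) {
  fmt_pts <- function(m) if (is.null(m)) "" else
    paste(apply(m, 1, function(r) sprintf("%.3f,%.3f,%.3f", r[1], r[2], r[3])), collapse = ";")
  lines <- c(
    sprintf("rng_seed=%d", system$rng_seed),
    sprintf("n_res=%d", nrow(system$ca_coords)),
    sprintf("resolution=%.3f", system$resolution),
    sprintf("noise_sigma=%.5f", system$noise_sigma),
    sprintf("sequence=%s", system$sequence %||% ""),
    sprintf("ca_coords=%s", fmt_pts(system$ca_coords)),
    sprintf("ligand_coords=%s", fmt_pts(system$ligand_coords)),
    sprintf("water_coords=%s", fmt_pts(system$water_coords)),
    sprintf("blob_coords=%s", fmt_pts(system$blob_coords)))
  writeLines(lines, path)
  invisible(path)
}
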