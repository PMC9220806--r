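#' Pseudoatom sets
#'
#' A `pseudoatom_set` holds exactly `n_target` 3D points reduced from
#' above-threshold map density. Pseudoatoms are Calpha surrogates and serve
#' as the nodes of the traveling-salesperson stage.
#'
#' @name pseudoatoms
NULL

new_pseudoatom_set <- function(coords, n_target, threshold = NA_real_,
                               noise_level = 0, method = "kmeans", seed = NA_integer_) {
  coords <- as_coords(coords)
  structure(list(coords = coords, n_target = as.integer(n_target),
                 threshold = threshold, noise_level = noise_level,
                 method = method, seed = seed), class = "pseudoatom_set")
}

#' @export
print.pseudoatom_set <- function(x, ...) {
  cat(sprintf("pseudoatom_set: %d points (method %s, threshold %.4g, noise %.3g A)\n",
              nrow(x$coords), x$method, x$threshold, x$noise_level))
  invisible(x)
}

#' Seed pseudoatoms in a density map
#'
#' Reduces the voxels above `threshold` to exactly `nres` points by
#' clustering the above-threshold voxel centers, weighted by their density
#' values. Cluster representatives are density-weighted cluster centroids.
#'
#' Methods: `kmeans` (weighted Lloyd with k-means++ start), `sc` (spectral
#' clustering), `ac` (agglomerative, Ward), `ms` (mean shift), `gmm`
#' (Gaussian-mixture means). Mean shift and agglomerative clustering do not
#' naturally produce a requested cluster count; the count is reconciled to
#' exactly `nres` by 2-means splitting of the heaviest clusters or merging of
#' the closest pair. Maps with more than `max_candidates` above-threshold
#' voxels are reduced by density-weighted sampling before clustering.
#'
#' @param grid a [density_grid].
#' @param threshold density threshold (map units); at least `nres` voxels
#'   must lie above it.
#' @param nres number of pseudoatoms, usually the expected residue count.
#' @param method one of `"kmeans"`, `"sc"`, `"ac"`, `"ms"`, `"gmm"`.
#' @param seed RNG seed (clustering initialization and subsampling).
#' @param max_candidates cap on candidate voxels before clustering.
#' @return A `pseudoatom_set` with exactly `nres` coordinates.
#' @export
seed_pseudoatoms <- function(grid, threshold, nres,
                             method = c("kmeans", "sc", "ac", "ms", "gmm"),
                             seed = 0, max_candidates = 2e5) {
  check_grid(grid)
  method <- match.arg(method)
  nres <- as.integer(nres)
  cand <- above_threshold_voxels(grid, threshold)
  n_cand <- nrow(cand$coords)
  if (n_cand < nres)
    stop(sprintf("threshold %.4g leaves only %d voxels above it; %d pseudoatoms requested",
                 threshold, n_cand, nres))
  with_seed(seed, {
    x <- cand$coords
    w <- cand$values
    if (any(w <= 0)) w <- w - min(w) + 1e-6 * max(abs(w), 1)  # negative-threshold guard
    if (n_cand > max_candidates) {
      idx <- sample.int(n_cand, max_candidates, prob = w)
      x <- x[idx, , drop = FALSE]; w <- w[idx]
    }
    res <- switch(method,
      kmeans = weighted_kmeans_best(x, w, nres),
      gmm = weighted_gmm(x, w, nres),
      ac = ward_cluster(x, w, nres),
      sc = spectral_cluster(x, w, nres),
      ms = {
        bw <- 2 * min(grid$voxel_size)
        r <- mean_shift_cluster(x, w, bandwidth = bw)
        reconcile_cluster_count(x, w, r$assign, r$centers, nres)
      })
    if (nrow(res$centers) != nres || length(unique(res$assign)) != nres)
      res <- reconcile_cluster_count(x, w, res$assign, res$centers, nres)
    centers <- t(vapply(seq_len(nres), function(c) {
      m <- res$assign == c
      colSums(x[m, , drop = FALSE] * w[m]) / sum(w[m])
    }, numeric(3)))
    new_pseudoatom_set(centers, nres, threshold = threshold, method = method,
                       seed = seed)
  })
}

#' Perturb pseudoatom positions
#'
#' Displaces every pseudoatom by isotropic zero-mean Gaussian noise of
#' per-axis standard deviation `noise_level` (Angstrom). Used to build decoy
#' libraries.
#'
#' @param pa a `pseudoatom_set`.
#' @param noise_level per-axis displacement standard deviation, Angstrom.
#' @param seed RNG seed.
#' @return A perturbed `pseudoatom_set` of identical size.
#' @export
perturb_positions <- function(pa, noise_level, seed = 0) {
  if (!inherits(pa, "pseudoatom_set")) stop("pa must be a pseudoatom_set")
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (noise_level == 0) { pa$noise_level <- 0; return(pa) }
  n <- nrow(pa$coords)
  pa$coords <- pa$coords + with_seed(seed, matrix(stats::rnorm(3 * n, sd = noise_level), n, 3))
  pa$noise_level <- noise_level
  pa
}

#' Write pseudoatoms as a Calpha-only PDB
#'
#' One CA-named atom per sequential residue number.
#'
#' @param pa a `pseudoatom_set` (or plain coordinate matrix).
#' @param path output path.
#' @param bfactor optional per-atom B-factor values.
#' @return Invisibly, `path`.
#' @export
write_pseudoatoms <- function(pa, path, bfactor = 0) {
  coords <- if (inherits(pa, "pseudoatom_set")) pa$coords else as_coords(pa)
  write_pdb(ca_atom_table(coords, bfactor = bfactor), path)
}

#' Load pseudoatoms from a Calpha-only PDB
#'
#' Accepts files with exactly one atom per residue (e.g. Calpha-only models
#' produced by any modeling tool, in the map's coordinate frame) so external
#' models can be scored with the decoy-ensemble machinery. Multi-atom
#' residues are rejected.
#'
#' @param path path to the PDB file.
#' @return A `pseudoatom_set`.
#' @export
load_pseudoatoms <- function(path) {
  atoms <- read_pdb(path)
  if (nrow(atoms) == 0L) stop(sprintf("no coordinates in %s", path))
  key <- paste(atoms$chain, atoms$resseq)
  if (anyDuplicated(key))
    stop("input must be a Calpha-only model: found residues with multiple atoms")
  new_pseudoatom_set(cbind(atoms$x, atoms$y, atoms$z), nrow(atoms),
                     method = "loaded")
}
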