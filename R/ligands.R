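#' Residual-density ligand and water detection
#'
#' After a protein model is built, density it does not explain may belong to
#' waters, ions, or larger ligands. The residual-density pipeline: (1) mask
#' map density near the protein model, (2) seed one candidate point per
#' remaining above-threshold voxel (the candidate count is data-driven, not
#' user-specified), (3) filter candidates by distance to the model and, when
#' half-maps are available, by half-map voxel consistency, (4) cluster the
#' survivors by mean shift, (5) classify each cluster by size and shape as a
#' water/ion or a ligand, and (6) emit two coordinate files and two masked
#' maps (one pair for ligands, one for waters/ions).
#'
#' @name ligand_finder
NULL

#' Default maximum model distance (Angstrom) for residual points
#' @export
default_model_dist <- 5

#' Default mean-shift bandwidth weight
#' @export
default_bandwidth_weight <- 10

#' Default protein mask radius (Angstrom) before residual seeding
#' @export
default_mask_radius <- 2.0

#' Seed candidate points in residual density
#'
#' Masks the map within `mask_radius` of the model, then places one candidate
#' point at the center of every remaining voxel above `threshold`.
#'
#' @param grid a [density_grid].
#' @param model_atoms n x 3 model atom coordinates (Angstrom).
#' @param threshold density threshold (map units).
#' @param mask_radius protein mask radius, Angstrom (default 2).
#' @return A list of class `residual_cloud`: `points` (m x 3),
#'   `density_value` per point, `voxel_index` per point.
#' @export
seed_residual <- function(grid, model_atoms, threshold,
                          mask_radius = default_mask_radius) {
  check_grid(grid)
  model_atoms <- as_coords(model_atoms)
  if (nrow(model_atoms) == 0L) stop("model must be non-empty")
  if (threshold >= max(grid$values))
    warning("threshold at or above map maximum: no residual voxels")
  masked <- mask_near_model(grid, model_atoms, mask_radius)
  cand <- above_threshold_voxels(masked, threshold)
  if (nrow(cand$coords) == 0L)
    warning("no residual density above threshold after masking")
  structure(list(points = cand$coords, density_value = cand$values,
                 voxel_index = cand$index),
            class = "residual_cloud")
}

#' Filter residual points by model distance and half-map consistency
#'
#' Removes points farther than `model_dist` from every model atom, and, when
#' half-maps are given, points whose voxel fails the half-map consistency
#' test at `half_thresh` (sigma of the full map). Without half-maps only the
#' distance filter applies (with a warning).
#'
#' @param cloud a `residual_cloud`.
#' @param model_atoms n x 3 model atom coordinates.
#' @param model_dist maximum model distance, Angstrom (default 5).
#' @param half1,half2 optional half-map [density_grid]s, congruent with the
#'   map the cloud was seeded from.
#' @param half_thresh half-map difference threshold in map-sigma units.
#' @param grid the full map (supplies the sigma unit and voxel frame); when
#'   `NULL`, sigma comes from the half-map average.
#' @return The filtered `residual_cloud`, with `model_distance` and
#'   `halfmap_ok` recorded per retained point and `n_removed` bookkeeping.
#' @export
filter_points <- function(cloud, model_atoms, model_dist = default_model_dist,
                          half1 = NULL, half2 = NULL,
                          half_thresh = default_half_thresh, grid = NULL) {
  if (!inherits(cloud, "residual_cloud")) stop("cloud must be a residual_cloud")
  n0 <- nrow(cloud$points)
  if (n0 == 0L) { cloud$n_removed <- c(distance = 0L, halfmap = 0L); return(cloud) }
  model_atoms <- as_coords(model_atoms)
  md <- min_dist_to(cloud$points, model_atoms)
  keep_d <- md <= model_dist

  keep_h <- rep(TRUE, n0)
  if (!is.null(half1) && !is.null(half2)) {
    check_congruent(half1, half2)
    if (!is.null(grid)) check_congruent(grid, half1)
    sigma <- if (!is.null(grid)) grid$sigma else NULL
    ok_mask <- halfmap_consistency(half1, half2, half_thresh, sigma = sigma)
    keep_h <- ok_mask[cloud$voxel_index]
  } else {
    warning("no half-maps provided: half-map consistency filter skipped")
  }
  keep <- keep_d & keep_h
  structure(list(points = cloud$points[keep, , drop = FALSE],
                 density_value = cloud$density_value[keep],
                 voxel_index = cloud$voxel_index[keep],
                 model_distance = md[keep],
                 halfmap_ok = rep(TRUE, sum(keep)),
                 n_removed = c(distance = sum(!keep_d),
                               halfmap = sum(keep_d & !keep_h))),
            class = "residual_cloud")
}

#' Cluster residual points by mean shift
#'
#' Bandwidth is derived from the user-facing `bandwidth_weight` as
#' `bandwidth_weight * min(voxel_size) / 10` Angstrom, so the default weight
#' of 10 gives a one-voxel bandwidth; higher-resolution (finer) maps thus
#' call for larger weights. After mode seeking, clusters whose member point
#' sets come within one bandwidth of each other are merged, so density
#' regions that are connected at the bandwidth scale (e.g. an elongated
#' ligand ridge) form a single cluster. Per-cluster descriptors: a
#' density-weighted center, sorted PCA eigenvalues of the member coordinates,
#' and the extent (maximum pairwise member distance).
#'
#' @param cloud a `residual_cloud` with at least one point.
#' @param bandwidth_weight bandwidth estimator weight (default 10).
#' @param voxel_size voxel edge used in the bandwidth formula; taken from the
#'   seeding grid in pipeline use.
#' @return A list of `density_cluster` objects, each with `members`,
#'   `weights`, `center`, `pca_eigenvalues`, `extent`, and `label = NA`.
#' @export
cluster_points <- function(cloud, bandwidth_weight = default_bandwidth_weight,
                           voxel_size = 1) {
  if (!inherits(cloud, "residual_cloud")) stop("cloud must be a residual_cloud")
  n <- nrow(cloud$points)
  if (n < 1L) stop("need at least one point to cluster")
  bw <- bandwidth_weight * min(voxel_size) / 10
  ms <- mean_shift_cluster(cloud$points, cloud$density_value, bandwidth = bw)
  assign <- merge_connected_clusters(cloud$points, ms$assign, link_dist = bw)
  labs <- sort(unique(assign))
  lapply(labs, function(c) {
    m <- assign == c
    pts <- cloud$points[m, , drop = FALSE]
    w <- cloud$density_value[m]
    center <- colSums(pts * w) / sum(w)
    ev <- if (nrow(pts) >= 2) {
      e <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
      sort(pmax(e, 0), decreasing = TRUE)
    } else c(0, 0, 0)
    extent <- if (nrow(pts) >= 2) max(stats::dist(pts)) else 0
    structure(list(members = pts, weights = w, center = center,
                   pca_eigenvalues = ev, extent = extent, label = NA_character_),
              class = "density_cluster")
  })
}

# single-linkage consolidation of clusters whose member sets approach within
# `link_dist` of each other
merge_connected_clusters <- function(points, assign, link_dist) {
  labs <- sort(unique(assign))
  k <- length(labs)
  if (k <= 1) return(match(assign, labs))
  assign <- match(assign, labs)
  parent <- seq_len(k)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (a in seq_len(k - 1)) {
    pa <- points[assign == a, , drop = FALSE]
    for (b in (a + 1):k) {
      pb <- points[assign == b, , drop = FALSE]
      if (min(FNN::get.knnx(pb, pa, k = 1L)$nn.dist) <= link_dist) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, sort(unique(roots)))[assign]
}

#' Classify clusters as waters/ions or ligands
#'
#' Size-and-shape rule: a cluster is a `water_ion` iff its extent is at most
#' `water_extent_max` (default 2.5 Angstrom, boundary inclusive) and it has
#' at most `water_members_max` members; everything larger or more extended is
#' a `ligand`. Because residual seeding places one point per voxel, the
#' member count of a genuine water blob scales with voxel volume (a 2.5
#' Angstrom blob holds ~10-15 points at 1 Angstrom sampling), so the extent
#' is the operative, scale-free criterion and the member cap defaults to a
#' loose sanity bound of 60. Waters and ions are not distinguished from each
#' other. The rule is deterministic and order-independent.
#'
#' @param clusters list of `density_cluster` objects.
#' @param water_extent_max extent cutoff, Angstrom.
#' @param water_members_max member-count cutoff.
#' @return The clusters with `label` filled in.
#' @export
classify_clusters <- function(clusters, water_extent_max = 2.5,
                              water_members_max = 60) {
  lapply(clusters, function(cl) {
    cl$label <- if (cl$extent <= water_extent_max &&
                    nrow(cl$members) <= water_members_max) "water_ion" else "ligand"
    cl
  })
}

#' Emit classified-results files
#'
#' Writes the standard result set: a waters/ions PDB (HOH oxygen records at
#' cluster centers), a ligand-points PDB (one chain of dummy carbon atoms per
#' ligand cluster), and two masked maps -- the input grid zeroed except
#' within `mask_pad` (2 Angstrom) of ligand member points, and the analogous
#' water map.
#'
#' @param grid the full [density_grid].
#' @param clusters classified clusters from [classify_clusters()].
#' @param out_prefix output path prefix; files are
#'   `<prefix>_ligands.pdb`, `<prefix>_waters.pdb`,
#'   `<prefix>_ligands.mrc`, `<prefix>_waters.mrc`.
#' @param mask_pad masking radius around cluster points, Angstrom.
#' @return Named character vector of the four file paths.
#' @export
emit_results <- function(grid, clusters, out_prefix, mask_pad = 2) {
  check_grid(grid)
  labels <- vapply(clusters, function(cl) cl$label, character(1))
  if (anyNA(labels)) stop("clusters must be classified before emitting results")
  lig <- clusters[labels == "ligand"]
  wat <- clusters[labels == "water_ion"]

  lig_pdb <- paste0(out_prefix, "_ligands.pdb")
  wat_pdb <- paste0(out_prefix, "_waters.pdb")
  lig_map <- paste0(out_prefix, "_ligands.mrc")
  wat_map <- paste0(out_prefix, "_waters.mrc")

  # waters: one HOH oxygen per cluster center
  if (length(wat)) {
    centers <- do.call(rbind, lapply(wat, function(cl) cl$center))
    tab <- data.frame(record = "HETATM", serial = seq_len(nrow(centers)),
                      name = "O", resname = "HOH", chain = "W",
                      resseq = seq_len(nrow(centers)),
                      x = centers[, 1], y = centers[, 2], z = centers[, 3],
                      occ = 1, bfactor = 0, element = "O",
                      stringsAsFactors = FALSE)
    write_pdb(tab, wat_pdb)
  } else write_pdb(data.frame(), wat_pdb)

  # ligands: dummy atoms for every member point, one chain per cluster
  if (length(lig)) {
    tabs <- lapply(seq_along(lig), function(ci) {
      pts <- lig[[ci]]$members
      data.frame(record = "HETATM", serial = seq_len(nrow(pts)),
                 name = "C", resname = "UNK", chain = LETTERS[(ci - 1) %% 26 + 1],
                 resseq = ci, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 occ = 1, bfactor = 0, element = "C", stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    tab$serial <- seq_len(nrow(tab))
    write_pdb(tab, lig_pdb)
  } else write_pdb(data.frame(), lig_pdb)

  keep_map <- function(pts) {
    if (is.null(pts) || nrow(pts) == 0L) {
      return(density_grid(array(0, dim(grid$values)), grid$voxel_size, grid$origin))
    }
    zeroed <- mask_near_model(grid, pts, mask_pad)   # zero NEAR points
    density_grid(grid$values - zeroed$values, grid$voxel_size, grid$origin)
  }
  write_map(keep_map(if (length(lig)) do.call(rbind, lapply(lig, `[[`, "members"))), lig_map)
  write_map(keep_map(if (length(wat)) do.call(rbind, lapply(wat, `[[`, "members"))), wat_map)
  c(ligand_pdb = lig_pdb, water_pdb = wat_pdb,
    ligand_map = lig_map, water_map = wat_map)
}

#' Correlation-based template fit score
#'
#' Simulates density from the posed template atoms with the package's
#' Gaussian kernel (on the map's own lattice) and returns the Pearson
#' correlation with the map over voxels within 3 Angstrom of the posed
#' template. Invariant under linear rescaling of the map.
#'
#' @param template_atoms n x 3 template coordinates (Angstrom).
#' @param grid the [density_grid] to score against.
#' @param pose optional rigid pose: `list(R = 3x3 rotation, t = length-3
#'   translation)` applied as `x R^T + t`; identity by default.
#' @param resolution kernel resolution for the simulated template density.
#' @return Pearson correlation in [-1, 1].
#' @export
score_template_fit <- function(template_atoms, grid, pose = NULL, resolution = 4) {
  check_grid(grid)
  template_atoms <- as_coords(template_atoms)
  if (nrow(template_atoms) == 0L) stop("template must be non-empty")
  if (!is.null(pose)) {
    R <- pose$R %||% diag(3)
    t <- pose$t %||% c(0, 0, 0)
    template_atoms <- sweep(template_atoms %*% t(R), 2, t, "+")
  }
  d <- dim(grid$values)
  lo <- grid$origin
  hi <- grid$origin + (d - 1) * grid$voxel_size
  if (any(t(template_atoms) < lo) || any(t(template_atoms) > hi))
    stop("pose places template outside the grid")
  sim <- simulate_map_onto(density_grid(array(0, d), grid$voxel_size, grid$origin),
                           template_atoms, resolution)
  # voxels within 3 A of the template
  sel_grid <- mask_near_model(density_grid(array(1, d), grid$voxel_size, grid$origin),
                              template_atoms, 3)
  sel <- sel_grid$values == 0
  a <- grid$values[sel]; b <- sim$values[sel]
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
  stats::cor(a, b)
}
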