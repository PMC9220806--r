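# residual-density seeding, filtering, clustering, classification, output

test_that("seed_residual is empty under a full mask and monotone in threshold", {
  sys <- hth_system(30, 1)
  # model covering all density: every Calpha, generous mask
  expect_warning(cloud <- seed_residual(sys$map, sys$ca_coords, 0.25,
                                        mask_radius = 30), "no residual")
  expect_identical(nrow(cloud$points), 0L)
  sysp <- planted_system(1)
  c1 <- seed_residual(sysp$map, sysp$ca_coords, 0.25)
  c2 <- seed_residual(sysp$map, sysp$ca_coords, 0.4)
  expect_lte(nrow(c2$points), nrow(c1$points))
  # every planted ligand point has a candidate within one voxel
  d <- captrace:::min_dist_to(sysp$ligand_coords, c1$points)
  expect_lt(max(d), 1.0)
})

test_that("filter_points applies distance and half-map rules", {
  sysp <- planted_system(1)
  cloud <- seed_residual(sysp$map, sysp$ca_coords, 0.3)
  # distance rule: a synthetic point 6 A beyond the chain's top disappears
  # at model_dist 5
  top <- sysp$ca_coords[which.max(sysp$ca_coords[, 3]), ]
  far_pt <- matrix(top + c(0, 0, 6), 1)
  stopifnot(min(captrace:::min_dist_to(far_pt, sysp$ca_coords)) > 5)
  far <- cloud
  far$points <- rbind(far$points, far_pt)
  far$density_value <- c(far$density_value, 1)
  far$voxel_index <- c(far$voxel_index, far$voxel_index[1])
  kept <- filter_points(far, sysp$ca_coords, model_dist = 5,
                        half1 = sysp$half1, half2 = sysp$half2, grid = sysp$map)
  expect_gt(min(captrace:::min_dist_to(far_pt, kept$points)), 0.1)
  expect_true(all(kept$model_distance <= 5))
  # the half1-only blob is removed entirely; ligand points survive
  filt <- filter_points(cloud, sysp$ca_coords, model_dist = 5,
                        half1 = sysp$half1, half2 = sysp$half2, grid = sysp$map)
  expect_gt(filt$n_removed[["halfmap"]], 0)
  d_blob <- captrace:::min_dist_to(filt$points, sysp$blob_coords)
  expect_gt(min(d_blob), 1.5)
  d_lig <- captrace:::min_dist_to(sysp$ligand_coords, filt$points)
  expect_lt(max(d_lig), 1.0)
  # filtering never adds points
  expect_lte(nrow(filt$points), nrow(cloud$points))
  # without half-maps, only the distance rule applies (warning)
  expect_warning(nof <- filter_points(cloud, sysp$ca_coords, model_dist = 5),
                 "half-map")
  expect_gte(nrow(nof$points), nrow(filt$points))
  # congruence errors surface
  bad <- density_grid(array(0, c(4, 4, 4)))
  expect_error(filter_points(cloud, sysp$ca_coords, 5, bad, sysp$half2),
               "congruent")
})

test_that("mean-shift clustering separates planted blobs", {
  pts <- rbind(matrix(rnorm(60, sd = 0.5), 20, 3),
               sweep(matrix(rnorm(60, sd = 0.5), 20, 3), 2, c(15, 0, 0), "+"))
  set.seed(1)
  cloud <- structure(list(points = pts, density_value = rep(1, 40),
                          voxel_index = seq_len(40)), class = "residual_cloud")
  cl <- cluster_points(cloud, bandwidth_weight = 10, voxel_size = 1)
  expect_length(cl, 2)
  centers <- t(vapply(cl, `[[`, numeric(3), "center"))
  d <- captrace:::min_dist_to(rbind(c(0, 0, 0), c(15, 0, 0)), centers)
  expect_lt(max(d), 1.5)
  # memberships partition the cloud
  expect_identical(sum(vapply(cl, function(x) nrow(x$members), integer(1))), 40L)
  # eigenvalues sorted, extent consistent
  for (x in cl) {
    expect_true(all(diff(x$pca_eigenvalues) <= 1e-9))
    expect_equal(x$extent, max(stats::dist(x$members)), tolerance = 1e-9)
  }
  # a single isolated point is a singleton cluster of extent 0
  single <- structure(list(points = matrix(c(1, 2, 3), 1),
                           density_value = 1, voxel_index = 1L),
                      class = "residual_cloud")
  cs <- cluster_points(single)
  expect_length(cs, 1)
  expect_identical(cs[[1]]$extent, 0)
  expect_identical(default_bandwidth_weight, 10)
})

test_that("classification is a deterministic size/shape rule", {
  mk <- function(pts) {
    pts <- as.matrix(pts)
    structure(list(members = pts, weights = rep(1, nrow(pts)),
                   center = colMeans(pts),
                   pca_eigenvalues = sort(eigen(stats::cov(rbind(pts, pts)))$values,
                                          decreasing = TRUE),
                   extent = if (nrow(pts) > 1) max(stats::dist(pts)) else 0,
                   label = NA_character_), class = "density_cluster")
  }
  singleton <- mk(matrix(c(0, 0, 0), 1))
  boundary <- mk(rbind(c(0, 0, 0), c(2.5, 0, 0), c(1.25, 0, 0)))  # extent exactly 2.5
  elongated <- mk(cbind(seq(0, 15.4, length.out = 12), 0, 0))
  out <- classify_clusters(list(singleton, boundary, elongated))
  expect_identical(vapply(out, `[[`, character(1), "label"),
                   c("water_ion", "water_ion", "ligand"))
  # order independence
  out2 <- classify_clusters(list(elongated, singleton, boundary))
  expect_identical(vapply(out2, `[[`, character(1), "label"),
                   c("ligand", "water_ion", "water_ion"))
})

test_that("emit_results writes exactly two PDBs and two maps with masked density", {
  tmp <- withr::local_tempdir()
  sysp <- planted_system(1)
  cloud <- seed_residual(sysp$map, sysp$ca_coords, 0.3)
  filt <- filter_points(cloud, sysp$ca_coords, 5, sysp$half1, sysp$half2,
                        grid = sysp$map)
  cl <- classify_clusters(cluster_points(filt, 10, sysp$map$voxel_size))
  files <- emit_results(sysp$map, cl, file.path(tmp, "out"))
  expect_length(files, 4)
  expect_true(all(file.exists(files)))
  labs <- vapply(cl, `[[`, character(1), "label")
  waters <- read_pdb(files[["water_pdb"]])
  expect_identical(nrow(waters), sum(labs == "water_ion"))
  expect_true(all(waters$resname == "HOH"))
  # brute-force check: every nonzero ligand-map voxel is within 2 A of a
  # ligand member point
  lig_map <- read_map(files[["ligand_map"]])
  nz <- which(lig_map$values != 0)
  lig_pts <- do.call(rbind, lapply(cl[labs == "ligand"], `[[`, "members"))
  nz_xyz <- voxel_to_world(lig_map, arrayInd(nz, dim(lig_map$values)))
  expect_lte(max(captrace:::min_dist_to(nz_xyz, lig_pts)), 2 + 1e-5)
  # empty class: no ligand clusters -> all-zero ligand map, empty PDB
  files0 <- emit_results(sysp$map, cl[labs == "water_ion"], file.path(tmp, "w"))
  expect_identical(sum(read_map(files0[["ligand_map"]])$values != 0), 0L)
  expect_identical(nrow(read_pdb(files0[["ligand_pdb"]])), 0L)
})

test_that("template fit scoring behaves like a correlation", {
  template <- make_ca_trace(8, "strand")
  g <- simulate_map(template, 4, 1, pad = 14)
  expect_gte(score_template_fit(template, g), 0.99)
  # linear rescaling of the map leaves the score unchanged
  g2 <- density_grid(3.5 * g$values + 0.2, g$voxel_size, g$origin)
  expect_equal(score_template_fit(template, g2), score_template_fit(template, g),
               tolerance = 1e-9)
  # translated into empty density: |r| small
  pose <- list(R = diag(3), t = c(0, 10, 0))
  expect_lt(abs(score_template_fit(template, g, pose)), 0.2)
  # poses leaving the grid raise an error
  expect_error(score_template_fit(template, g, list(R = diag(3), t = c(500, 0, 0))),
               "outside")
  expect_error(score_template_fit(matrix(numeric(0), 0, 3), g), "non-empty")
})

test_that("the planted system is recovered end to end", {
  sysp <- planted_system(2)
  cloud <- seed_residual(sysp$map, sysp$ca_coords, 0.3)
  filt <- filter_points(cloud, sysp$ca_coords, 5, sysp$half1, sysp$half2,
                        grid = sysp$map)
  cl <- classify_clusters(cluster_points(filt, 10, sysp$map$voxel_size))
  labs <- vapply(cl, `[[`, character(1), "label")
  lig <- cl[labs == "ligand"]
  expect_length(lig, 1)
  expect_lt(sqrt(sum((lig[[1]]$center - colMeans(sysp$ligand_coords))^2)), 2)
  wc <- do.call(rbind, lapply(cl[labs == "water_ion"], `[[`, "center"))
  n_rec <- sum(captrace:::min_dist_to(sysp$water_coords, wc) <= 1)
  expect_gte(n_rec, 4)
  # nothing clusters at the inconsistent blob
  allc <- do.call(rbind, lapply(cl, `[[`, "center"))
  expect_gt(min(captrace:::min_dist_to(matrix(colMeans(sysp$blob_coords), 1), allc)), 2)
})
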