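# decoy ensembles, averaging, connectivity probabilities, B-factor output

# hand-built ensembles reuse the package's own list structure
fake_decoy <- function(coords, order) {
  list(pa = captrace:::new_pseudoatom_set(coords, nrow(coords)),
       path = structure(list(order = order,
                             total_length = sum(sqrt(rowSums(diff(coords[order, ])^2)))),
                        class = "backbone_path"))
}

fake_ensemble <- function(decoys, reference = 1L) {
  structure(list(decoys = decoys, thresholds = NA, noise_levels = NA,
                 reference_index = reference), class = "decoy_ensemble")
}

test_that("decoy count is thresholds x noise levels", {
  sys <- hth_system(30, 1)
  m <- sys$map
  ens <- generate_decoys(m, 0.3, bracket = c(0.25, 0.35, 0.05),
                         noise_levels = c(0, 0.5, 1), nres = 20, base_seed = 1)
  expect_length(ens$decoys, 3 * 3)
  expect_identical(length(ens$thresholds), 3L)
  # degenerate ensemble: single threshold, zero noise = one plain run
  ens1 <- generate_decoys(m, 0.3, bracket = c(0.3, 0.3, 1), noise_levels = 0,
                          nres = 20, base_seed = 1)
  expect_length(ens1$decoys, 1L)
  pa <- seed_pseudoatoms(m, 0.3, 20, "kmeans", seed = 1L + 1000L)
  plain <- solve_open(build_edge_matrix(pa))
  expect_identical(ens1$decoys[[1]]$path$order, plain$order)
  # over-high bracket thresholds are reported by value
  expect_error(generate_decoys(m, 0.3, bracket = c(0.3, max(m$values) + 1,
                                                   max(m$values)),
                               noise_levels = 0, nres = 20), "threshold")
})

test_that("averaging identical decoys returns their coordinates", {
  set.seed(2)
  coords <- matrix(runif(30) * 20, 10, 3)
  ord <- sample(10)
  e <- fake_ensemble(replicate(4, fake_decoy(coords, ord), simplify = FALSE))
  mod <- correspond_and_average(e)
  expect_equal(mod$avg_coords, coords, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("mirrored perturbations average back to the truth", {
  truth <- make_ca_trace(12, "helix")
  set.seed(3)
  delta <- matrix(rnorm(36, sd = 0.4), 12, 3)
  # decoys store rows in shuffled order to exercise the correspondence step
  shuf <- sample(12)
  d1 <- fake_decoy(truth + delta, 1:12)
  d2 <- fake_decoy((truth - delta)[shuf, ], order(shuf))
  mod <- correspond_and_average(fake_ensemble(list(d1, d2)))
  expect_equal(mod$avg_coords, truth, tolerance = 1e-6, ignore_attr = TRUE)
  # the optimal bijection never costs more than the identity mapping
  cost_identity <- sum((truth + delta - (truth - delta)[shuf, ][1:12, ])^2)
  map2 <- mod$correspondence[[2]]
  cost_opt <- sum(((truth + delta) - (truth - delta)[shuf, ][map2, ])^2)
  expect_lte(cost_opt, cost_identity + 1e-9)
})

test_that("connectivity probabilities have the stated semantics", {
  coords <- make_ca_trace(8, "strand")
  base <- 1:8
  # all decoys identical: 100 everywhere
  e <- fake_ensemble(replicate(4, fake_decoy(coords, base), simplify = FALSE))
  mod <- connectivity_probability(correspond_and_average(e), e)
  expect_identical(mod$probability, rep(100, 8))

  # 2 of 4 decoys exchange the path positions of non-adjacent interior nodes
  # 3 and 6 (path 1-2-6-4-5-3-7-8): in those decoys both swapped nodes lose
  # both of their average-path neighbors, so they score (1 + 1 + 0 + 0)/4 = 50%
  swapped <- base; swapped[c(3, 6)] <- c(6L, 3L)
  e2 <- fake_ensemble(list(fake_decoy(coords, base), fake_decoy(coords, base),
                           fake_decoy(coords, swapped), fake_decoy(coords, swapped)))
  mod2 <- correspond_and_average(e2)
  # mean coords are on the strand, so the solved average path is the strand
  expect_identical(sort(mod2$avg_path$order[c(1, 8)]), c(1L, 8L))
  mod2 <- connectivity_probability(mod2, e2)
  expect_equal(mod2$probability[3], 50)
  expect_equal(mod2$probability[6], 50)
  expect_true(all(mod2$probability >= 0 & mod2$probability <= 100))
  # flanking nodes keep one of their two neighbors in the swapped decoys
  expect_equal(mod2$probability[c(2, 4, 5, 7)], rep(75, 4))
  # untouched termini stay fully confident
  expect_equal(mod2$probability[c(1, 8)], c(100, 100))
})

test_that("noisier ensembles have lower consensus; termini trail interiors", {
  sys <- hth_system(30, 2)
  m <- sys$map
  run <- function(noise_max) {
    ens <- generate_decoys(m, 0.3, bracket = c(0.27, 0.33, 0.03),
                           noise_levels = seq(0, noise_max, length.out = 6),
                           nres = 30, base_seed = 3)
    connectivity_probability(correspond_and_average(ens), ens)
  }
  lo <- run(1); hi <- run(5)
  expect_lte(mean(hi$probability), mean(lo$probability))
  # zero-noise single-threshold ensembles are fully confident
  ens0 <- generate_decoys(m, 0.3, bracket = c(0.3, 0.3, 1), noise_levels = 0,
                          nres = 30, base_seed = 4)
  mod0 <- connectivity_probability(correspond_and_average(ens0), ens0)
  expect_identical(mod0$probability, rep(100, 30))
})

test_that("probabilistic PDB output is strict fixed-column PDB", {
  tmp <- withr::local_tempdir()
  coords <- make_ca_trace(6, "helix")
  e <- fake_ensemble(replicate(3, fake_decoy(coords, 1:6), simplify = FALSE))
  mod <- connectivity_probability(correspond_and_average(e), e)
  mod$probability <- c(100, 87.654, 50, 33.333, 0, 75.5)
  f <- file.path(tmp, "prob.pdb")
  write_probabilistic_pdb(mod, f)
  lines <- grep("^ATOM", readLines(f), value = TRUE)
  expect_length(lines, 6)
  # strict column offsets (PDB v3.3): name cols 13-16, x 31-38, B 61-66
  expect_true(all(substr(lines, 13, 16) == " CA "))
  expect_true(all(nchar(lines) >= 78))
  b <- as.numeric(substr(lines, 61, 66))
  ord <- mod$avg_path$order
  expect_equal(b, mod$probability[ord], tolerance = 0.005)
  expect_identical(substr(lines[match(1, ord)], 61, 66), "100.00")
  # round-trip through the reader
  expect_equal(read_pdb(f)$bfactor, mod$probability[ord], tolerance = 0.005)
})
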