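# edge matrices, TSP solving, path opening, refinement

test_that("build_edge_matrix is Euclidean without map weighting", {
  set.seed(1)
  x <- matrix(runif(15) * 10, 5, 3)
  em <- build_edge_matrix(x)
  expect_equal(em$weights, as.matrix(stats::dist(x)), ignore_attr = TRUE)
  expect_false(em$map_weighted)
  expect_error(build_edge_matrix(x, map_weight = TRUE), "grid")
  expect_error(build_edge_matrix(x[1:2, ]), "3 nodes")
})

test_that("density weighting penalizes exactly the gap-crossing segments", {
  # two blobs with a clean gap plus a third point inside blob 1
  g <- simulate_map(rbind(c(0, 0, 0), c(14, 0, 0)), 4, 1)
  pts <- rbind(c(0, 0, 0), c(0.8, 0, 0), c(14, 0, 0))
  tau <- 0.2
  pa <- captrace:::new_pseudoatom_set(pts, 3, threshold = tau)
  em <- build_edge_matrix(pa, grid = g, map_weight = TRUE)
  euc <- as.matrix(stats::dist(pts))
  # within-blob segment: density stays above tau -> no penalty
  expect_equal(em$weights[1, 2], euc[1, 2], tolerance = 1e-9)
  # blob-to-blob segments cross near-zero density -> strictly longer
  expect_gt(em$weights[1, 3], euc[1, 3])
  expect_gt(em$weights[2, 3], euc[2, 3])
  # direct sampling oracle: minimum density along the 1-3 segment
  t <- seq(0, 1, length.out = 29)
  seg <- outer(1 - t, pts[1, ]) + outer(t, pts[3, ])
  rho <- min(captrace:::interp_density(g, seg))
  expect_equal(em$weights[1, 3], euc[1, 3] * (1 + 2 * max(0, 1 - rho / tau)),
               tolerance = 1e-9)
})

test_that("solve_cycle equals the brute-force optimum for small instances", {
  set.seed(42)
  for (r in 1:8) {
    n <- sample(5:9, 1)
    w <- as.matrix(stats::dist(matrix(runif(n * 3) * 12, n, 3)))
    expect_equal(tour_len(solve_cycle(w), w), brute_force_cycle_length(w),
                 tolerance = 1e-9)
  }
})

test_that("solver is deterministic and never worse than greedy", {
  set.seed(5)
  x <- matrix(runif(90) * 20, 30, 3)
  w <- as.matrix(stats::dist(x))
  t1 <- solve_cycle(w)
  expect_identical(t1, solve_cycle(w))
  expect_lte(tour_len(t1, w), tour_len(captrace:::greedy_tour(w), w))
  expect_identical(sort(t1), 1:30)        # Hamiltonian
  # default time cap is 30 s
  expect_identical(default_tsp_time, 30)
})

test_that("open_path deletes the heaviest edge with index tie-breaks", {
  # collinear points with one large terminal gap
  x <- cbind(c(0, 3, 6, 20), 0, 0)
  em <- build_edge_matrix(x)
  tour <- solve_cycle(em$weights)
  p <- open_path(tour, em)
  expect_setequal(c(p$order[1], p$order[4]), c(1, 4))   # gap flanks the cut
  expect_equal(p$total_length, 3 + 3 + 14, tolerance = 1e-9)
  expect_lte(p$total_length, tour_len(tour, em$weights))
  # equilateral triangle: all edges tie; cut the smallest (i, j) pair (1,2)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  emt <- build_edge_matrix(tri)
  pt <- open_path(c(1L, 2L, 3L), emt)
  expect_setequal(c(pt$order[1], pt$order[3]), c(1, 2))
})

test_that("open_path endpoints maximize the deleted edge weight", {
  set.seed(11)
  x <- matrix(runif(24) * 10, 8, 3)
  em <- build_edge_matrix(x)
  tour <- solve_cycle(em$weights)
  p <- open_path(tour, em)
  deleted <- tour_len(tour, em$weights) - p$total_length
  nxt <- c(tour[-1], tour[1])
  expect_equal(deleted, max(em$weights[cbind(tour, nxt)]), tolerance = 1e-9)
})

test_that("solve_open recovers the chain where cycle-cutting cannot", {
  ca <- make_ca_trace(30, "helix")
  em <- build_edge_matrix(ca)
  po <- solve_open(em)
  expect_true(all(po$order == 1:30) || all(po$order == 30:1))
  expect_equal(po$total_length, 29 * 3.8, tolerance = 1e-6)
  # the raw minimum cycle on the same instance is a ladder: cutting its
  # heaviest edge does not yield the chain (this is why the dummy node exists)
  pc <- open_path(solve_cycle(em), em)
  expect_gt(pc$total_length, po$total_length)
})

test_that("refine_path is a fixed point on ideal traces and repairs displacements", {
  ca <- make_ca_trace(25, "helix")
  m <- simulate_map(ca, 4, 1)
  pa <- captrace:::new_pseudoatom_set(ca, 25, threshold = 0.3)
  path <- structure(list(order = 1:25, total_length = 24 * 3.8),
                    class = "backbone_path")
  r <- refine_path(path, pa, m, rounds = 3)
  expect_lt(max(sqrt(rowSums((r$pa$coords - ca)^2))), 0.05)

  pa2 <- pa
  pa2$coords[12, ] <- pa2$coords[12, ] + c(1.5, 0, 0)
  r2 <- refine_path(path, pa2, m, rounds = 3)
  d_after <- min(sqrt(rowSums(sweep(ca, 2, r2$pa$coords[12, ])^2)))
  expect_lt(d_after, 1.5)
  # consecutive-distance spread does not grow
  sd_before <- stats::sd(sqrt(rowSums(diff(pa2$coords)^2)))
  sd_after <- stats::sd(sqrt(rowSums(diff(r2$pa$coords[r2$path$order, ])^2)))
  expect_lte(sd_after, sd_before)
  # mean deviation from 3.8 A does not grow either
  dev <- function(x) mean(abs(sqrt(rowSums(diff(x)^2)) - 3.8))
  expect_lte(dev(r2$pa$coords[r2$path$order, ]), dev(pa2$coords))
  expect_error(refine_path(path, pa, m, rounds = 0), "rounds")
})
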