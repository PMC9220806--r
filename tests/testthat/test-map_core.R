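# map I/O, filtering, masking, half-map consistency

test_that("MRC round-trip preserves values and geometry", {
  tmp <- withr::local_tempdir()
  set.seed(1)
  g <- density_grid(array(rnorm(20^3), c(20, 20, 20)),
                    voxel_size = c(1.0, 1.1, 1.2), origin = c(5.0, -3.0, 0.0))
  f <- file.path(tmp, "g.mrc")
  write_map(g, f)
  g2 <- read_map(f)
  expect_lt(max(abs(g$values - g2$values)), 1e-6)   # float32 precision
  expect_equal(g2$voxel_size, g$voxel_size, tolerance = 1e-6)
  expect_equal(g2$origin, g$origin, tolerance = 1e-5)
  # writing the re-read grid reproduces the file bit-for-bit
  f2 <- file.path(tmp, "g2.mrc")
  write_map(g2, f2)
  g3 <- read_map(f2)
  expect_identical(g3$values, g2$values)
})

test_that("constant zero map reads back with zero mean and sigma", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "z.mrc")
  write_map(density_grid(array(0, c(16, 16, 16))), f)
  g <- read_map(f)
  expect_identical(g$mean, 0)
  expect_identical(g$sigma, 0)
})

test_that("permuted axis-order files normalize to the canonical volume", {
  tmp <- withr::local_tempdir()
  set.seed(2)
  g <- density_grid(array(rnorm(12 * 14 * 16), c(12, 14, 16)),
                    voxel_size = c(0.9, 1.0, 1.1), origin = c(1, 2, 3))
  ref <- read_map(write_map(g, file.path(tmp, "ref.mrc")))
  for (ord in list(c(2, 1, 3), c(3, 1, 2), c(1, 3, 2), c(3, 2, 1))) {
    got <- read_map(write_map(g, file.path(tmp, "perm.mrc"), axis_order = ord))
    expect_identical(got$values, ref$values)
    expect_equal(got$voxel_size, ref$voxel_size, tolerance = 1e-6)
  }
})

test_that("unreadable or malformed map files raise format errors", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "junk.mrc")
  writeBin(as.raw(rep(7, 100)), f)
  expect_error(read_map(f), "truncated|readable")
  expect_error(read_map(file.path(tmp, "absent.mrc")), "not found")
})

test_that("lowpass_filter matches its analytic transfer function", {
  # pure sinusoid of 3 A period along x on a 1 A grid, filtered at 4.5 A:
  # H = exp(-(4.5/3)^2)
  n <- 48
  x <- (0:(n - 1))
  wave <- sin(2 * pi * x / 3)
  v <- array(rep(wave, times = n * n), c(n, n, n))
  g <- density_grid(v)
  filt <- lowpass_filter(g, 4.5)
  h_expected <- exp(-(4.5 / 3)^2)
  ratio <- as.vector(filt$values) / as.vector(v)
  ratio <- ratio[abs(as.vector(v)) > 0.5]
  expect_equal(mean(ratio), h_expected, tolerance = 1e-6)
  expect_lt(stats::sd(ratio), 1e-6)
})

test_that("lowpass_filter preserves constants and never raises power", {
  g <- density_grid(array(2.5, c(16, 16, 16)))
  f <- lowpass_filter(g, 4.5)
  expect_equal(f$values, g$values, tolerance = 1e-12)
  set.seed(3)
  g2 <- density_grid(array(rnorm(16^3), c(16, 16, 16)))
  f2 <- lowpass_filter(g2, 5)
  expect_lte(sum(f2$values^2), sum(g2$values^2))
  expect_equal(f2$mean, g2$mean, tolerance = 1e-12)
  expect_error(lowpass_filter(g2, 1.9), "Nyquist")
})

test_that("default low-pass resolution is 4.5 Angstrom", {
  expect_identical(default_lowpass_resolution, 4.5)
})

test_that("mask_near_model zeroes exactly the voxels a brute-force scan finds", {
  set.seed(4)
  g <- density_grid(array(runif(18^3) + 0.1, c(18, 18, 18)))
  atom <- matrix(c(7, 9, 11), 1)  # on a voxel center (origin 0, voxel 1)
  r <- 1.5
  masked <- mask_near_model(g, atom, r)
  idx <- arrayInd(seq_along(g$values), dim(g$values))
  d <- sqrt(rowSums(sweep(idx - 1, 2, atom[1, ])^2))
  expect_identical(which(masked$values == 0), which(d <= r))
  # idempotent, pointwise dominated
  again <- mask_near_model(masked, atom, r)
  expect_identical(again$values, masked$values)
  expect_true(all(abs(masked$values) <= abs(g$values)))
})

test_that("mask_near_model handles radius zero and empty models", {
  g <- density_grid(array(1, c(8, 8, 8)))
  expect_identical(mask_near_model(g, matrix(c(3, 3, 3), 1), 0)$values, g$values)
  expect_warning(out <- mask_near_model(g, matrix(numeric(0), 0, 3), 2), "empty")
  expect_identical(out$values, g$values)
})

test_that("halfmap_consistency applies the sigma-unit threshold voxelwise", {
  set.seed(5)
  base <- array(rnorm(12^3), c(12, 12, 12))
  h1 <- density_grid(base)
  expect_true(all(halfmap_consistency(h1, h1, 0.5)))

  sigma <- stats::sd(as.vector(base))
  pert <- base
  pert[3, 4, 5] <- pert[3, 4, 5] + 1.0 * sigma
  h2 <- density_grid(pert)
  keep <- halfmap_consistency(h1, h2, 0.5, sigma = sigma)
  expect_false(keep[3, 4, 5])
  expect_equal(sum(!keep), 1L)
  # symmetry in the two half-map arguments
  expect_identical(keep, halfmap_consistency(h2, h1, 0.5, sigma = sigma))
  # default threshold is 0.5 sigma
  expect_identical(default_half_thresh, 0.5)
  bad <- density_grid(array(0, c(6, 6, 6)))
  expect_error(halfmap_consistency(h1, bad), "congruent")
})
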