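test_that("a delta phantom reproduces its system-matrix column exactly", {
  sm <- small_matrix()
  g <- small_grid()
  vals <- array(0, g$shape); vals[5, 5, 5] <- 2.5
  delta <- voxel_grid(g$shape, g$voxel_mm, values = vals)
  raw <- acquire(sm, delta, seed = 1)
  v <- which(as.vector(vals) > 0)
  expect_equal(raw$spectra[, 1], 2.5 * sm$S[, v])
})

test_that("noiseless acquisition is linear in the concentration map", {
  sm <- small_matrix()
  g <- small_grid()
  c1 <- voxelize(single_tube_phantom(3, 5), g)
  c2 <- voxelize(single_tube_phantom(1, 10), g)
  both <- voxel_grid(g$shape, g$voxel_mm, values = c1$values + c2$values)
  u1 <- acquire(sm, c1, seed = 1)$spectra[, 1]
  u2 <- acquire(sm, c2, seed = 1)$spectra[, 1]
  u12 <- acquire(sm, both, seed = 1)$spectra[, 1]
  expect_equal(u12, u1 + u2, tolerance = 1e-12)
})

test_that("mirror-symmetric voxels give equal spectral magnitudes", {
  # divisors chosen so every per-axis period count over the closed
  # trajectory is odd: the drive flips sign after half a trajectory, so
  # voxels mirrored through the FFP center respond with equal magnitude
  cfg <- scanner_config(divisors = c(9L, 15L, 5L))
  g <- voxel_grid(c(7, 7, 7), c(3.5, 3.5, 1.75))
  sm <- build_system_matrix(cfg, reference_tracer(), g)
  idx <- function(i, j, k) i + 7 * (j - 1) + 49 * (k - 1)
  a <- sm$S[, idx(2, 3, 5)]
  b <- sm$S[, idx(6, 5, 3)]  # point mirrored through the grid center
  expect_equal(Mod(a), Mod(b), tolerance = 1e-8)
})

test_that("acquisitions are bit-reproducible for a fixed seed", {
  sm <- calibrate_noise(small_matrix(), 30)
  tg <- voxelize(single_tube_phantom(3, 1), small_grid())
  r1 <- acquire(sm, tg, seed = 42)
  r2 <- acquire(sm, tg, seed = 42)
  expect_identical(r1$spectra, r2$spectra)
  expect_identical(r1$background, r2$background)
  r3 <- acquire(sm, tg, seed = 43)
  expect_false(identical(r1$spectra, r3$spectra))
})

test_that("frame averaging reduces the noise standard deviation by sqrt(frames)", {
  sm <- calibrate_noise(small_matrix(), 30)
  empty <- voxel_grid(small_grid()$shape, small_grid()$voxel_mm)
  ratios <- vapply(1:30, function(s) {
    r <- acquire(sm, empty, seed = s)
    stats::sd(Re(r$spectra[, 1])) / stats::sd(Re(rowMeans(r$spectra)))
  }, 0)
  expect_equal(mean(ratios), sqrt(5), tolerance = 0.10)
})

test_that("an empty phantom is statistically indistinguishable from background", {
  sm <- calibrate_noise(small_matrix(), 30)
  empty <- voxel_grid(small_grid()$shape, small_grid()$voxel_mm)
  r <- acquire(sm, empty, seed = 99)
  ks <- suppressWarnings(stats::ks.test(Re(r$spectra[1:200, 1]),
                                        Re(r$background[1:200, 1])))
  expect_gt(ks$p.value, 0.01)
})

test_that("frequency selection honors the SNR threshold and is monotone", {
  sm <- calibrate_noise(small_matrix(), 30)
  all_rows <- select_frequencies(sm, snr_threshold = 0)
  expect_equal(nrow(all_rows$S), nrow(sm$S))
  n6 <- nrow(select_frequencies(sm, snr_threshold = 6)$S)
  n24 <- nrow(select_frequencies(sm, snr_threshold = 24)$S)
  expect_lte(n24, n6)
  expect_lte(n6, nrow(sm$S))
  expect_error(select_frequencies(sm, snr_threshold = Inf), "empty selection")
  # row order preserved
  sel <- select_frequencies(sm, snr_threshold = 6)
  expect_true(!is.unsorted(attr(sel, "selected")))
})

test_that("system-matrix generation is deterministic for a fixed configuration", {
  cfg <- scanner_config()
  g <- voxel_grid(c(5, 5, 5), c(4, 4, 2))
  s1 <- build_system_matrix(cfg, reference_tracer(), g)
  s2 <- build_system_matrix(cfg, reference_tracer(), g)
  expect_identical(s1$S, s2$S)
})

test_that("scanner bundles survive an RDS round trip", {
  sm <- small_matrix()
  path <- withr::local_tempfile(fileext = ".rds")
  save_bundle(sm, path)
  back <- load_bundle(path)
  expect_identical(back$S, sm$S)
  expect_identical(back$rows, sm$rows)
})
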