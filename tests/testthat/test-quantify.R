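# A clean synthetic "reconstruction": binary cylinder along x on the desk grid.
cylinder_volume <- function(level = 10, noise_sd = 0, seed = 1) {
  g <- voxel_grid()
  tg <- voxelize(single_tube_phantom(3, level), g)
  vals <- tg$values
  mask <- vals >= 0.5 * max(vals)
  vals[] <- 0; vals[mask] <- level
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- pmax(vals + stats::rnorm(length(vals), 0, noise_sd), 0)
    dim(vals) <- g$shape
  }
  list(vol = voxel_grid(g$shape, g$voxel_mm, values = vals), truth = mask)
}

test_that("an already-binary cylinder is segmented exactly", {
  cv <- cylinder_volume()
  sg <- segment(cv$vol, axis = 1)
  expect_false(sg$failed)
  expect_identical(sg$object, cv$truth)
})

test_that("segmentation of a noisy cylinder stays close to the ground truth", {
  cv <- cylinder_volume(level = 10, noise_sd = 1, seed = 7)  # 10% of peak
  sg <- segment(cv$vol, axis = 1)
  dice <- 2 * sum(sg$object & cv$truth) / (sum(sg$object) + sum(cv$truth))
  expect_gt(dice, 0.9)
})

test_that("degenerate volumes are flagged, not silently segmented", {
  g <- voxel_grid(c(7, 7, 7), c(1, 1, 1))
  zero <- segment(g)
  expect_true(zero$failed)
  uniform <- segment(voxel_grid(g$shape, g$voxel_mm,
                                values = array(3, g$shape)))
  expect_true(uniform$failed)
  expect_true(volume_and_iron(g, zero)$flagged)
  expect_true(is.na(snr(g, zero)))
})

test_that("segmentation is deterministic", {
  cv <- cylinder_volume(level = 10, noise_sd = 1, seed = 3)
  s1 <- segment(cv$vol, axis = 1)
  s2 <- segment(cv$vol, axis = 1)
  expect_identical(s1$object, s2$object)
})

test_that("SNR is the object/background mean ratio and is scale invariant", {
  cv <- cylinder_volume()
  v <- cv$vol
  v$values[!cv$truth] <- 1  # flat unit background
  sg <- segment(v, axis = 1)
  expect_equal(snr(v, sg), 10, tolerance = 1e-9)
  v2 <- v; v2$values <- v$values * 37.5
  expect_equal(snr(v2, segment(v2, axis = 1)), snr(v, sg))
  # zero background flagged as infinite, and equal levels give 1
  vz <- cv$vol
  expect_equal(as.numeric(snr(vz, segment(vz, axis = 1))), Inf)
  seg_manual <- structure(list(object = cv$truth, background = !cv$truth,
                               failed = FALSE), class = "segmentation")
  vflat <- voxel_grid(v$shape, v$voxel_mm, values = array(4, dim(v$values)))
  expect_equal(snr(vflat, seg_manual), 1)
})

test_that("volume and iron quantification is exact on ground-truth grids", {
  g <- full_scale_grid()
  for (d in c(1, 2, 3)) {
    fill <- switch(as.character(d), "1" = 10, "2" = 40, "3" = 90)
    tg <- voxelize(single_tube_phantom(d, 5), g)
    seg_all <- structure(list(object = tg$values > 0,
                              background = tg$values == 0, failed = FALSE),
                         class = "segmentation")
    q <- volume_and_iron(tg, seg_all, fill, 5 * fill * 1e-3)
    expect_equal(q$volume_ul, sum(tg$values > 0) * prod(g$voxel_mm))
    expect_lt(abs(q$iron_umol / (5 * fill * 1e-3) - 1), 0.01)
  }
})

test_that("lambda sweep returns a per-lambda table and a defensible optimum", {
  sm <- desk_matrix()
  tg <- voxelize(single_tube_phantom(3, 10), voxel_grid())
  corr <- background_subtract(acquire(sm, tg, seed = 1))
  sw <- lambda_sweep(sm, corr, lambdas = c(1e-1, 1e-3, 1e-5), axis = 1)
  expect_equal(nrow(sw$table), 3)
  expect_true(sw$best_lambda %in% sw$table$lambda)
  # noiseless: the best SNR is attained at (or tied with) the optimum
  valid <- !sw$table$failed
  expect_equal(max(sw$table$snr[valid]), sw$table$snr[sw$table$lambda ==
                                                        sw$best_lambda])
  expect_error(lambda_sweep(sm, corr, lambdas = 1e-2), "2")
})

test_that("dual-tube metrics report iron ratios, symmetry and separation", {
  g <- voxel_grid()
  ph33 <- dual_tube_phantom(c(3, 3), 10, gap_mm = 6)
  tg <- voxelize(ph33, g)
  dt <- dual_tube_metrics(tg, ph33)
  expect_equal(dt$iron_ratio, 1)
  expect_equal(dt$shadowing_ratio, 1, tolerance = 0.05)
  expect_true(dt$separable)
  expect_equal(dual_tube_metrics(tg, dual_tube_phantom(c(3, 1), 10))$iron_ratio, 9)
  expect_equal(dual_tube_metrics(tg, dual_tube_phantom(c(2, 1), 10))$iron_ratio, 4)
  expect_error(dual_tube_metrics(tg, single_tube_phantom(3, 10)), "dual")
})

test_that("maximum intensity projections match a brute-force oracle", {
  set.seed(4)
  g <- voxel_grid(c(6, 5, 4), c(1, 1, 1),
                  values = array(stats::runif(120), c(6, 5, 4)))
  for (ax in 1:3) {
    mip <- mip_render(g, threshold_fraction = 0, axis = ax)
    oth <- setdiff(1:3, ax)
    oracle <- matrix(0, g$shape[oth[1]], g$shape[oth[2]])
    for (i in seq_len(g$shape[oth[1]])) for (j in seq_len(g$shape[oth[2]]))
      oracle[i, j] <- max(vapply(seq_len(g$shape[ax]), function(k) {
        idx <- integer(3); idx[ax] <- k; idx[oth] <- c(i, j)
        g$values[idx[1], idx[2], idx[3]]
      }, 0))
    expect_equal(mip, oracle)
  }
  # single bright voxel projects to a single bright pixel
  v <- array(0, c(6, 5, 4)); v[2, 3, 1] <- 7
  m <- mip_render(voxel_grid(c(6, 5, 4), c(1, 1, 1), values = v), 0.5, axis = 3)
  expect_equal(which(m > 0), which(matrix(seq_len(30), 6, 5) == 2 + 6 * 2))
  expect_equal(max(m), 7)
  # thresholding zeroes sub-threshold structure
  m2 <- mip_render(g, threshold_fraction = 0.99, axis = 3)
  expect_lt(sum(m2 > 0), sum(mip_render(g, 0, 3) > 0))
})
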