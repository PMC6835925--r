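truth <- reference_tracer()

test_that("background subtraction removes a known blank exactly and via interpolation", {
  fields <- mh_field_grid(40)
  signal <- mh_forward(truth, fields)
  zero_blank <- magnetization_curve(fields, rep(0, length(fields)))
  expect_equal(subtract_background(signal, zero_blank)$magnetization,
               signal$magnetization)
  # linear diamagnetic blank chi*H on a finer grid: interpolation recovery
  chi <- -1e-5 / (4e-7 * pi)  # per A/m, expressed against B in T
  fine <- mh_field_grid(160)
  blank <- magnetization_curve(fine, chi * fine)
  raw <- magnetization_curve(fields, signal$magnetization + chi * fields)
  rec <- subtract_background(raw, blank)
  expect_equal(rec$magnetization, signal$magnetization, tolerance = 1e-6)
  # non-overlapping ranges rejected
  narrow <- magnetization_curve(seq(1, 2, length.out = 10), rep(0, 10))
  expect_error(subtract_background(signal, narrow), "range")
})

test_that("fitted saturation magnetization is unbiased after blank subtraction", {
  fields <- mh_field_grid(50)
  signal <- mh_forward(truth, fields)
  chi <- -1e-5 / (4e-7 * pi)
  raw <- magnetization_curve(fields, signal$magnetization + chi * fields)
  blank <- magnetization_curve(fields, chi * fields)
  fit <- fit_mh(subtract_background(raw, blank))
  expect_lt(abs(fit$distribution$ms_molar / truth$ms_molar - 1), 0.01)
})

test_that("noiseless parameter recovery succeeds from perturbed initializations", {
  curve <- mh_forward(truth, mh_field_grid(50))
  for (seed in 1:5) {
    set.seed(seed)
    f <- function(x) x * runif(1, 0.8, 1.2)
    init <- moment_distribution(min(f(truth$beta), 1), f(truth$mu1),
                                f(truth$mu2), f(truth$sigma1),
                                f(truth$sigma2), f(truth$ms_molar))
    fit <- fit_mh(curve, init)
    expect_true(fit$converged)
    expect_equal(fit$distribution$beta, truth$beta, tolerance = 1e-4)
    expect_equal(fit$distribution$mu2, truth$mu2, tolerance = 1e-4)
    expect_equal(fit$distribution$sigma2, truth$sigma2, tolerance = 1e-3)
    expect_equal(fit$distribution$ms_molar, truth$ms_molar, tolerance = 1e-4)
  }
})

test_that("refitting a model-generated curve is self-consistent", {
  curve <- mh_forward(truth, mh_field_grid(50))
  fit <- fit_mh(curve)
  refit_curve <- mh_forward(fit$distribution, curve$field_t)
  fit2 <- fit_mh(refit_curve, fit$distribution)
  expect_lt(fit2$residual_norm, 1e-8 * sqrt(sum(curve$magnetization^2)))
  # estimated M_S at least the largest observed magnetization
  expect_gte(fit$distribution$ms_molar, max(abs(curve$magnetization)))
})

test_that("mode labels are ordered mu1 < mu2 regardless of initialization", {
  curve <- mh_forward(truth, mh_field_grid(50))
  swapped <- moment_distribution(1 - truth$beta, truth$mu2, truth$mu1,
                                 truth$sigma2, truth$sigma1, truth$ms_molar)
  fit <- fit_mh(curve, swapped)
  expect_lt(fit$distribution$mu1, fit$distribution$mu2)
  expect_equal(fit$distribution$beta, truth$beta, tolerance = 1e-3)
})

test_that("Monte-Carlo recovery under 1% noise keeps median errors below 5%", {
  fields <- mh_field_grid(30)
  base <- mh_forward(truth, fields)$magnetization
  errs <- t(vapply(1:25, function(s) {
    set.seed(s)
    noisy <- base * (1 + stats::rnorm(length(base), 0, 0.01))
    fit <- fit_mh(magnetization_curve(fields, noisy))
    c(abs(fit$distribution$beta - truth$beta),
      abs(fit$distribution$mu2 / truth$mu2 - 1))
  }, c(0, 0)))
  expect_lt(stats::median(errs[, 1]), 0.05)
  expect_lt(stats::median(errs[, 2]), 0.05)
})

test_that("summary derivation reports diameters, products and percent differences", {
  s <- derive_summary(truth, tem_mean_diameter_nm = 32)
  expect_equal(s$mode_b_volume_percent, 73)
  expect_equal(s$beta_mu2_aAm2, 0.73 * 3.9, tolerance = 1e-9)
  # with d_v2 = 27 nm exactly, the magnetic diameter is 16% below TEM
  ms <- mass_to_molar_magnetization(104)
  d27 <- moment_distribution(0.73, truth$mu1, diameter_to_moment(27, ms),
                             0.3, 0.13, ms)
  s27 <- derive_summary(d27, 32)
  expect_equal(round(s27$percent_smaller_than_tem), 16)
  # degenerate: all volume in mode B
  all_b <- moment_distribution(1, truth$mu1, truth$mu2, 0.3, 0.13, ms)
  expect_equal(derive_summary(all_b, 32)$mode_b_volume_percent, 100)
})

test_that("fit reports serialize to a structured key-value table", {
  fit <- fit_mh(mh_forward(truth, mh_field_grid(50)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_report(fit, path)
  rep <- utils::read.csv(path)
  expect_setequal(names(rep), c("key", "value", "uncertainty", "unit"))
  expect_equal(rep$value[rep$key == "beta"], 0.73, tolerance = 1e-3)
})
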