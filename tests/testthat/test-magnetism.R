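test_that("Langevin function is odd, bounded, increasing, with correct limits", {
  x <- c(1e-8, 1e-5, 0.01, 0.1, 1, 5, 9.11, 50)
  expect_equal(langevin(0), 0)
  expect_equal(langevin(-x), -langevin(x))
  expect_true(all(abs(langevin(c(-x, x))) < 1))
  expect_true(all(diff(langevin(seq(-20, 20, by = 0.05))) > 0))
  # small-argument limit xi/3
  expect_equal(langevin(0.01), 0.01 / 3, tolerance = 1e-4)
  # frozen from direct evaluation of coth(9.11) - 1/9.11
  expect_equal(langevin(9.11), 0.8902305, tolerance = 1e-6)
  # series and coth branches agree at the switch point
  expect_equal(langevin(0.01 * (1 - 1e-9)), langevin(0.01 * (1 + 1e-9)),
               tolerance = 1e-8)
})

test_that("mass/molar magnetization conversions round-trip and match printed pairs", {
  expect_equal(signif(mass_to_molar_magnetization(104), 2), 5.8)
  expect_equal(signif(mass_to_molar_magnetization(111), 2), 6.2)
  expect_equal(signif(mass_to_molar_magnetization(127), 2), 7.1)
  expect_equal(mass_to_molar_magnetization(0), 0)
  x <- c(0.5, 104, 333)
  expect_equal(molar_to_mass_magnetization(mass_to_molar_magnetization(x)), x)
  expect_error(mass_to_molar_magnetization(-1), "non-negative")
})

test_that("ferrous iron fractions follow mineral stoichiometry", {
  expect_equal(fe2plus_fraction("magnetite"), 100 / 3)
  expect_equal(fe2plus_fraction("maghemite"), 0)
  expect_equal(fe2plus_fraction("magnetite", magnetite_iron_fraction = 0.3),
               0.3 * 100 / 3)
  expect_error(fe2plus_fraction("wuestite"))
})

test_that("moment-diameter mapping inverts and scales as a sphere", {
  mc <- material_constants()
  ms <- mass_to_molar_magnetization(104, mc)
  d <- moment_to_diameter(3.9e-18, ms, mc)
  expect_equal(d, 27, tolerance = 0.05)
  mu <- c(0.2, 3.9, 40) * 1e-18
  expect_equal(diameter_to_moment(moment_to_diameter(mu, ms, mc), ms, mc),
               mu, tolerance = 1e-12)
  expect_equal(moment_to_diameter(2 * 3.9e-18, ms, mc) / d, 2^(1 / 3))
  expect_error(moment_to_diameter(0, ms, mc), "positive")
})

test_that("forward M(H) model saturates, vanishes at zero field, and is monotone", {
  dist <- reference_tracer()
  b <- mh_field_grid(60)
  curve <- mh_forward(dist, b)
  expect_s3_class(curve, "magnetization_curve")
  expect_equal(curve$magnetization[1], 0)
  expect_true(all(diff(curve$magnetization) >= 0))
  expect_lt(abs(curve$magnetization[length(b)] / dist$ms_molar - 1), 0.01)
  expect_true(all(curve$magnetization <= dist$ms_molar * (1 + 1e-9)))
  # odd in field
  expect_equal(mh_forward(dist, -0.02), -mh_forward(dist, 0.02))
})

test_that("degenerate single-mode distribution reduces to a pure Langevin curve", {
  ms <- 5.81
  dist <- moment_distribution(beta = 1, mu1 = 1e-19, mu2 = 3.9e-18,
                              sigma1 = 0, sigma2 = 0, ms_molar = ms)
  b <- c(1e-4, 1e-3, 1e-2, 0.1)
  kt <- material_constants()$boltzmann * 295
  expect_equal(mh_forward(dist, b)$magnetization,
               ms * langevin(3.9e-18 * b / kt), tolerance = 1e-8)
})

test_that("Gauss-Hermite quadrature matches a dense trapezoid oracle", {
  b <- c(1e-4, 1e-3, 0.01, 0.1, 1)
  for (prm in list(c(3.9e-18, 0.13), c(1.86e-19, 0.3))) {
    gh <- mpiphantom:::mode_mean_langevin(b, prm[1], prm[2], 295,
                                          material_constants(), 61)
    oracle <- trapezoid_mean_langevin(b, prm[1], prm[2], 295)
    expect_equal(gh, oracle, tolerance = 1e-6)
  }
  # node-count convergence
  gh2 <- mpiphantom:::mode_mean_langevin(b, 3.9e-18, 0.13, 295,
                                         material_constants(), 121)
  gh1 <- mpiphantom:::mode_mean_langevin(b, 3.9e-18, 0.13, 295,
                                         material_constants(), 61)
  expect_equal(gh1, gh2, tolerance = 1e-9)
})

test_that("magnetization curves survive a delimited-table round trip", {
  curve <- mh_forward(reference_tracer(), mh_field_grid(20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mh_table(curve, path)
  back <- read_mh_table(path)
  expect_equal(back$field_t, curve$field_t)
  expect_equal(back$magnetization, curve$magnetization)
  # A/m field column converts through mu0
  path2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(field_Am = curve$field_t / (4e-7 * pi),
                   magnetization_Am2_per_molFe = curve$magnetization)
  utils::write.table(df, path2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_mh_table(path2)$field_t, curve$field_t, tolerance = 1e-12)
})
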