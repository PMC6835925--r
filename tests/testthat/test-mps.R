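dist310 <- reference_tracer(temperature = 310)
proto <- drive_protocol()

test_that("equilibrium spectra contain only odd harmonics above numerical floor", {
  s <- simulate_mps(dist310, proto, full_spectrum = TRUE)
  all_h <- attr(s, "all_harmonics")
  even <- all_h$amplitude[all_h$k %% 2 == 0]
  m1 <- s$amplitude[s$harmonic == 1]
  expect_true(all(even < 1e-10 * m1))
  # amplitudes ordered for an equilibrium Langevin response
  expect_true(all(diff(s$amplitude) <= 0))
})

test_that("linear-regime response has negligible harmonic distortion", {
  tiny <- moment_distribution(0.73, 1e-21, 2e-21, 0.2, 0.13, 5.81,
                              temperature = 310)
  s <- simulate_mps(tiny, proto)
  expect_lt(s$amplitude[s$harmonic == 3] / s$amplitude[s$harmonic == 1], 1e-2)
})

test_that("harmonic amplitudes are independent of time resolution", {
  s1 <- simulate_mps(dist310, drive_protocol(samples_per_period = 1024))
  s2 <- simulate_mps(dist310, drive_protocol(samples_per_period = 2048))
  expect_equal(s1$amplitude, s2$amplitude, tolerance = 1e-6)
})

test_that("Debye relaxation damps every harmonic and M3 monotonically", {
  s0 <- simulate_mps(dist310, proto, relaxation_time = 0)
  taus <- c(5e-7, 1.5e-6, 4e-6)
  m3 <- vapply(taus, function(tau)
    simulate_mps(dist310, proto, relaxation_time = tau)$amplitude[2], 0)
  expect_true(all(diff(m3) < 0))
  expect_true(all(m3 < s0$amplitude[2]))
  st <- simulate_mps(dist310, proto, relaxation_time = 1.5e-6)
  r <- spectrum_ratio(s0, st)
  expect_true(all(r$ratio[r$reliable] >= 1 - 1e-9))
})

test_that("relaxed response matches an independent stiff ODE solver", {
  tau <- 2e-6
  s_rk <- simulate_mps(dist310, drive_protocol(samples_per_period = 1024),
                       relaxation_time = tau)
  # oracle: lsoda at tight tolerance on dM/dt = (M_eq(B(t)) - M)/tau
  n <- 1024; f <- proto$frequency
  b_fun <- function(t) proto$amplitude * sin(2 * pi * f * t)
  meq <- function(t) mh_forward(dist310, b_fun(t), 310)
  times <- seq(0, 6 / f, length.out = 6 * n + 1)
  sol <- deSolve::lsoda(c(M = 0), times,
                        function(t, y, p) list((meq(t) - y) / tau),
                        rtol = 1e-10, atol = 1e-12)
  last <- sol[(5 * n + 1):(6 * n), "M"]
  co <- stats::fft(last)
  amp <- 2 * Mod(co[2:(n / 2)]) / n
  expect_equal(s_rk$amplitude[1:5], amp[c(1, 3, 5, 7, 9)], tolerance = 1e-4)
})

test_that("the small-moment mode contributes marginally to the third harmonic", {
  both <- simulate_mps(dist310, proto)
  mode_a <- moment_distribution(1e-12, dist310$mu1, dist310$mu2,
                                dist310$sigma1, dist310$sigma2,
                                dist310$ms_molar * (1 - dist310$beta), 310)
  sa <- simulate_mps(mode_a, proto)
  expect_lt(sa$amplitude[2] / both$amplitude[2], 0.05)
})

test_that("spectrum ratios recover constructed scalings and reject mismatches", {
  a <- simulate_mps(dist310, proto)
  expect_equal(spectrum_ratio(a, a)$ratio, rep(1, length(a$harmonic)))
  b <- a; b$amplitude <- 5 * a$amplitude
  expect_equal(spectrum_ratio(b, a)$ratio, rep(5, length(a$harmonic)))
  other <- simulate_mps(dist310, drive_protocol(amplitude = 0.012))
  expect_error(spectrum_ratio(a, other), "protocol")
  # below-floor denominators flagged, not NaN
  c <- a; c$amplitude[c$amplitude < 1e-3] <- 0
  r <- spectrum_ratio(a, c, noise_floor = 1e-12)
  expect_true(any(!r$reliable))
  expect_false(any(is.nan(r$ratio)))
})

test_that("spectra survive a delimited-table round trip", {
  s <- simulate_mps(dist310, proto)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_table(s, path)
  back <- read_spectrum_table(path)
  expect_equal(back$harmonic, s$harmonic)
  expect_equal(back$amplitude, s$amplitude)
})
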