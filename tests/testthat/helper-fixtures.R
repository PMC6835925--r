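# Shared fixtures: built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

# Small desk-scale scanner: 9^3 grid covering the standard FOV, short
# Lissajous trajectory (1680 samples, still more rows than voxels).
# Cheap enough for most tests.
small_grid <- function() voxel_grid(c(9, 9, 9), c(3, 3, 1.5))

small_matrix <- function() {
  if (is.null(.fixtures$sm_small))
    .fixtures$sm_small <- build_system_matrix(
      scanner_config(divisors = c(16L, 15L, 14L)),
      reference_tracer(), small_grid())
  .fixtures$sm_small
}

# Default 17^3 test-scale matrix used by the end-to-end checks.
desk_matrix <- function() {
  if (is.null(.fixtures$sm_desk))
    .fixtures$sm_desk <- build_system_matrix(scanner_config(),
                                             reference_tracer(),
                                             voxel_grid())
  .fixtures$sm_desk
}

# Wrap a plain complex matrix as a system_matrix for solver tests.
as_system_matrix <- function(A) {
  structure(list(S = A,
                 rows = data.frame(channel = 1, k = seq_len(nrow(A)),
                                   frequency_hz = seq_len(nrow(A))),
                 row_snr = rep(Inf, nrow(A)),
                 config = scanner_config(),
                 grid_geom = voxel_grid(c(ncol(A), 1, 1), c(1, 1, 1))),
            class = "system_matrix")
}

# Independent trapezoid oracle for the lognormal-averaged Langevin response
# on a dense log-moment grid.
trapezoid_mean_langevin <- function(b, mean_mu, sigma, temperature,
                                    n_grid = 1e5) {
  kt <- 1.380649e-23 * temperature
  lg <- seq(log(mean_mu) - 10 * sigma, log(mean_mu) + 10 * sigma,
            length.out = n_grid)
  mu <- exp(lg)
  dens <- stats::dlnorm(mu, log(mean_mu) - sigma^2 / 2, sigma)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(mu))
  norm <- trap(dens)
  vapply(b, function(bb) trap(dens * langevin(mu * bb / kt)) / norm, 0)
}
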