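#' Field-free-point scanner configuration
#'
#' Settings of the synthetic FFP scanner: a three-axis sinusoidal drive field
#' sweeping the field-free point of a static selection-field gradient along a
#' Lissajous trajectory. Per-axis drive frequencies follow the divisor
#' convention `f_i = sample_rate / divisors[i]` with
#' `sample_rate = base_frequency * divisors[1]`, so the 3D trajectory closes
#' after `lcm(divisors)` samples. The default desk-scale configuration uses
#' divisors (32, 30, 27) at an 800 kHz sample rate (drive 25.0/26.7/29.6
#' kHz, trajectory of 4320 samples), dense enough that the in-band frequency
#' rows outnumber the voxels of the default 17^3 grid -- preserving the
#' overdetermined noiseless limit of the full-scale system.
#' `full_scale_scanner()` uses the preclinical convention of divisors
#' (102, 96, 99) at 2.55 MHz (~25 kHz in all axes, 53856 samples).
#'
#' @param drive_amplitude_t Per-axis drive amplitude in T (recycled to 3).
#' @param base_frequency_hz Nominal drive frequency of the first axis, Hz.
#' @param divisors Integer length-3 frequency divisors.
#' @param gradient_t_m Selection-field gradient (Gx, Gy, Gz) in T/m.
#' @param noise_sd Standard deviation of the real and imaginary part of the
#'   additive complex Gaussian noise per frequency component (signal units);
#'   0 for noiseless.
#' @param snr_threshold Row-SNR threshold for frequency selection.
#' @param bandwidth_hz Length-2 retained frequency band (Hz); components at
#'   frequency 0 are always discarded.
#' @param frames Number of signal frames acquired (and background frames).
#' @param block_average Block-averaging factor applied before reconstruction.
#' @return An object of class `scanner_config`.
#' @export
scanner_config <- function(drive_amplitude_t = 0.012,
                           base_frequency_hz = 25e3,
                           divisors = c(32L, 30L, 27L),
                           gradient_t_m = c(1.25, 1.25, 2.5),
                           noise_sd = 0,
                           snr_threshold = 0,
                           bandwidth_hz = NULL,
                           frames = 5L,
                           block_average = 5L) {
  divisors <- as.integer(divisors)
  stopifnot(length(divisors) == 3, all(divisors >= 2),
            base_frequency_hz > 0, all(gradient_t_m > 0),
            noise_sd >= 0, frames >= 1, block_average >= 1)
  amp <- rep_len(drive_amplitude_t, 3)
  stopifnot(all(amp > 0))
  fs <- base_frequency_hz * divisors[1]
  if (is.null(bandwidth_hz)) bandwidth_hz <- c(0, fs / 2)
  stopifnot(length(bandwidth_hz) == 2, bandwidth_hz[2] > bandwidth_hz[1])
  structure(list(drive_amplitude_t = amp,
                 base_frequency_hz = base_frequency_hz,
                 divisors = divisors,
                 sample_rate_hz = fs,
                 drive_frequencies_hz = fs / divisors,
                 gradient_t_m = gradient_t_m,
                 noise_sd = noise_sd,
                 snr_threshold = snr_threshold,
                 bandwidth_hz = bandwidth_hz,
                 frames = as.integer(frames),
                 block_average = as.integer(block_average)),
            class = "scanner_config")
}

#' @rdname scanner_config
#' @param ... Overrides passed to [scanner_config()].
#' @export
full_scale_scanner <- function(...) {
  args <- list(divisors = c(102L, 96L, 99L), ...)
  do.call(scanner_config, args)
}

#' @export
print.scanner_config <- function(x, ...) {
  cat("FFP scanner configuration\n")
  cat(sprintf("  drive: %s mT at %s kHz\n",
              paste(format(x$drive_amplitude_t * 1e3), collapse = "/"),
              paste(sprintf("%.2f", x$drive_frequencies_hz / 1e3), collapse = "/")))
  cat(sprintf("  gradient: %s T/m; sample rate %.3g MHz; trajectory %d samples\n",
              paste(x$gradient_t_m, collapse = "/"), x$sample_rate_hz / 1e6,
              trajectory_samples(x)))
  cat(sprintf("  noise sd %.3g, SNR threshold %g, %d frames, block average %d\n",
              x$noise_sd, x$snr_threshold, x$frames, x$block_average))
  invisible(x)
}

# Least common multiple of the divisor triple = closed-trajectory length.
lcm2 <- function(a, b) a / pracma::gcd(a, b) * b
trajectory_samples <- function(config) {
  as.integer(lcm2(lcm2(config$divisors[1], config$divisors[2]),
                  config$divisors[3]))
}

#' Field-free-point trajectory
#'
#' World coordinates (mm) of the FFP over one closed Lissajous period,
#' `r_i(t) = A_i sin(2 pi f_i t) / G_i`.
#'
#' @param config A [scanner_config()].
#' @return A matrix (samples x 3) of FFP positions in mm.
#' @export
ffp_trajectory <- function(config) {
  n <- trajectory_samples(config)
  t <- (0:(n - 1)) / config$sample_rate_hz
  sapply(1:3, function(i) {
    config$drive_amplitude_t[i] * sin(2 * pi * config$drive_frequencies_hz[i] * t) /
      config$gradient_t_m[i] * 1e3
  })
}

#' Build the system matrix of the synthetic scanner
#'
#' Simulates, for a unit tracer concentration (1 mmol Fe/l) in each voxel, the
#' voltage signal induced in three ideal orthogonal receive channels while the
#' FFP traverses one closed Lissajous period. The field at a voxel is
#' `B_i(t) = G_i r_i - A_i sin(2 pi f_i t)`; the voxel's mean moment follows
#' the equilibrium magnetization of the tracer's moment distribution along
#' the local field direction, and the induced signal is its time derivative,
#' evaluated spectrally. Rows are frequency components within the configured
#' bandwidth for each receive channel; the magnetization lookup is
#' pre-tabulated over field magnitude for speed.
#'
#' @param config A [scanner_config()].
#' @param dist A [moment_distribution()] of the tracer.
#' @param grid A [voxel_grid()] giving the voxel geometry.
#' @param constants A [material_constants()] object.
#' @param nodes Quadrature nodes for the magnetization model.
#' @param chunk Voxels processed per block (memory/speed tradeoff).
#' @return An object of class `system_matrix`: list with complex matrix `S`
#'   (rows = selected components x voxels), `rows` (data.frame `channel`,
#'   `k`, `frequency_hz`), `row_snr`, and the generating `config`, `dist`,
#'   `grid_geom`.
#' @export
build_system_matrix <- function(config, dist, grid,
                                constants = material_constants(), nodes = 61,
                                chunk = 512L) {
  stopifnot(inherits(config, "scanner_config"),
            inherits(dist, "moment_distribution"),
            inherits(grid, "voxel_grid"))
  n <- trajectory_samples(config)
  t <- (0:(n - 1)) / config$sample_rate_hz
  drive <- sapply(1:3, function(i)
    config$drive_amplitude_t[i] *
      sin(2 * pi * config$drive_frequencies_hz[i] * t))  # n x 3, tesla

  # in-band frequency components (single-sided, DC excluded)
  freq <- (1:(n %/% 2)) * config$sample_rate_hz / n
  keep_k <- which(freq >= max(config$bandwidth_hz[1],
                              config$sample_rate_hz / n / 2) &
                    freq <= config$bandwidth_hz[2])
  if (!length(keep_k)) stop("bandwidth retains no frequency components")
  nk <- length(keep_k)

  # magnetization lookup over |B|
  xs <- grid_axis_coords(grid, 1) * 1e-3
  ys <- grid_axis_coords(grid, 2) * 1e-3
  zs <- grid_axis_coords(grid, 3) * 1e-3
  g <- config$gradient_t_m
  bmax <- sqrt(sum((abs(c(max(abs(xs)) * g[1], max(abs(ys)) * g[2],
                          max(abs(zs)) * g[3])) +
                      config$drive_amplitude_t)^2)) * 1.01
  b_tab <- seq(0, bmax, length.out = 4096)
  m_tab <- mh_forward(dist, b_tab, dist$temperature, constants, nodes)
  if (inherits(m_tab, "magnetization_curve")) m_tab <- m_tab$magnetization

  voxel_m3 <- prod(grid$voxel_mm) * 1e-9
  # moment per voxel at 1 mmol/l = 1 mol/m^3: M[Am^2/molFe] * c * V
  scale <- voxel_m3  # 1 mol/m^3 * m^3 = mol
  coords <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nvox <- nrow(coords)
  S <- matrix(complex(real = 0), nrow = 3 * nk, ncol = nvox)
  omega_k <- 2i * pi * freq[keep_k]
  starts <- seq(1, nvox, by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1, nvox)
    bx <- outer(-drive[, 1], g[1] * coords[idx, 1], "+")
    by <- outer(-drive[, 2], g[2] * coords[idx, 2], "+")
    bz <- outer(-drive[, 3], g[3] * coords[idx, 3], "+")
    bn <- sqrt(bx^2 + by^2 + bz^2)
    mm <- stats::approx(b_tab, m_tab, xout = pmin(as.vector(bn), bmax),
                        rule = 2)$y
    dim(mm) <- dim(bn)
    # scalar moment / |B|, safe at the FFP where M ~ chi*B -> finite ratio
    ratio <- ifelse(bn > 0, mm / bn, 0)
    for (ch in 1:3) {
      comp <- switch(ch, bx, by, bz) * ratio * scale
      sp <- stats::mvfft(comp)[keep_k + 1, , drop = FALSE] / n
      S[((ch - 1) * nk + 1):(ch * nk), idx] <- sp * omega_k
    }
  }
  rows <- data.frame(channel = rep(1:3, each = nk),
                     k = rep(keep_k, 3),
                     frequency_hz = rep(freq[keep_k], 3))
  row_rms <- sqrt(rowMeans(Mod(S)^2))
  row_snr <- if (config$noise_sd > 0) row_rms / config$noise_sd else
    rep(Inf, nrow(S))
  structure(list(S = S, rows = rows, row_snr = row_snr,
                 config = config, dist = dist,
                 grid_geom = voxel_grid(grid$shape, grid$voxel_mm,
                                        grid$origin_mm)),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("System matrix: %d frequency components x %d voxels (%d channels)\n",
              nrow(x$S), ncol(x$S), length(unique(x$rows$channel))))
  invisible(x)
}

#' Calibrate the noise level to a target mid-band row SNR
#'
#' Returns the complex-noise standard deviation at which the median in-band
#' system-function row reaches `target_snr`, and a copy of the matrix with
#' `row_snr` recomputed at that level.
#'
#' @param matrix A [build_system_matrix()] result.
#' @param target_snr Desired median row SNR (> 0).
#' @return The `system_matrix` with updated `row_snr` and
#'   `config$noise_sd`.
#' @export
calibrate_noise <- function(matrix, target_snr) {
  stopifnot(inherits(matrix, "system_matrix"), target_snr > 0)
  row_rms <- sqrt(rowMeans(Mod(matrix$S)^2))
  sd <- stats::median(row_rms) / target_snr
  matrix$config$noise_sd <- sd
  matrix$row_snr <- row_rms / sd
  matrix
}

#' Simulate a phantom acquisition
#'
#' Generates the measured frequency-domain signal `u = S c + eps` for each
#' frame, plus a paired background acquisition (noise only) of the same
#' length, mimicking the empty-bore background measurement taken before each
#' phantom measurement. Noise is additive complex Gaussian, stationary across
#' frames, with `config$noise_sd` as the standard deviation of the real and
#' imaginary parts. Deterministic for a given seed.
#'
#' @param matrix A `system_matrix`.
#' @param phantom_grid A [voxel_grid()] of concentrations on the matrix
#'   geometry.
#' @param seed Integer RNG seed.
#' @param config Scanner configuration (defaults to the matrix's).
#' @return An object of class `raw_signal`: complex matrices `spectra` and
#'   `background` (components x frames), `rows`, `seed`, `config`.
#' @export
acquire <- function(matrix, phantom_grid, seed = 1L, config = matrix$config) {
  stopifnot(inherits(matrix, "system_matrix"),
            inherits(phantom_grid, "voxel_grid"))
  geom <- matrix$grid_geom
  if (!all(phantom_grid$shape == geom$shape) ||
      !isTRUE(all.equal(phantom_grid$voxel_mm, geom$voxel_mm)))
    stop("phantom grid geometry does not match the system matrix")
  u0 <- as.vector(matrix$S %*% as.vector(phantom_grid$values))
  nr <- nrow(matrix$S); nf <- config$frames
  noise <- function() {
    if (config$noise_sd == 0) matrix(complex(real = 0), nr, nf) else
      matrix(complex(real = stats::rnorm(nr * nf, sd = config$noise_sd),
                     imaginary = stats::rnorm(nr * nf, sd = config$noise_sd)),
             nr, nf)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  spectra <- u0 + noise()
  background <- noise()
  structure(list(spectra = spectra, background = background,
                 rows = matrix$rows, seed = as.integer(seed),
                 config = config),
            class = "raw_signal")
}

#' Select system-matrix rows by SNR
#'
#' Retains the frequency components whose system-function row SNR meets the
#' threshold (row order preserved), emulating the SNR-thresholded frequency
#' selection applied before reconstruction.
#'
#' @param matrix A `system_matrix` with finite or infinite `row_snr`.
#' @param snr_threshold Minimum row SNR (defaults to the config's).
#' @return The `system_matrix` restricted to the selected rows; the selected
#'   row indices are attached as attribute `"selected"`.
#' @export
select_frequencies <- function(matrix,
                               snr_threshold = matrix$config$snr_threshold) {
  stopifnot(inherits(matrix, "system_matrix"))
  sel <- which(matrix$row_snr >= snr_threshold)
  if (!length(sel))
    stop("empty selection: no system-function row reaches SNR ",
         snr_threshold)
  out <- matrix
  out$S <- matrix$S[sel, , drop = FALSE]
  out$rows <- matrix$rows[sel, , drop = FALSE]
  out$row_snr <- matrix$row_snr[sel]
  attr(out, "selected") <- sel
  out
}
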