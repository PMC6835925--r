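#' Background subtraction and block averaging of a raw acquisition
#'
#' Subtracts the frame-averaged background spectrum from every signal frame,
#' then averages the corrected frames in blocks of the configured factor and
#' finally over blocks, yielding the single corrected spectrum used for
#' reconstruction.
#'
#' @param signal A `raw_signal` from [acquire()].
#' @param block_average Block size (defaults to the acquisition config's).
#' @return A list of class `corrected_spectrum` with `spectrum` (complex
#'   vector), `block_means` (components x blocks), `n_frames`, and `rows`.
#' @export
background_subtract <- function(signal,
                                block_average = signal$config$block_average) {
  stopifnot(inherits(signal, "raw_signal"))
  if (is.null(signal$background))
    stop("acquisition has no paired background measurement")
  nf <- ncol(signal$spectra)
  stopifnot(ncol(signal$background) == nf)
  bg <- rowMeans(signal$background)
  corrected <- signal$spectra - bg
  nblock <- max(1L, nf %/% block_average)
  use <- nblock * block_average
  if (use < 1 || use > nf) { nblock <- 1L; use <- nf }
  grp <- rep(seq_len(nblock), each = use %/% nblock, length.out = use)
  block_means <- sapply(seq_len(nblock), function(b)
    rowMeans(corrected[, which(grp == b), drop = FALSE]))
  if (is.null(dim(block_means)))
    block_means <- matrix(block_means, ncol = nblock)
  structure(list(spectrum = rowMeans(block_means),
                 block_means = block_means,
                 n_frames = nf, rows = signal$rows),
            class = "corrected_spectrum")
}

#' Regularized Kaczmarz reconstruction
#'
#' Solves the Tikhonov-regularized least-squares problem
#' `min_c ||S c - u||^2 + lambda_abs ||c||^2` by row-action sweeps over the
#' equivalent augmented system, the standard iterative scheme of MPI image
#' reconstruction. The regularization factor `lambda` is relative: it is
#' scaled by the mean row energy of the system matrix, so the familiar
#' 10^0 ... 10^-6 grid is meaningful across matrices. Rows are swept
#' sequentially in frequency order; after each sweep the iterate is
#' optionally projected onto real non-negative values (community convention
#' for tracer concentrations). Zero-energy rows are skipped.
#'
#' @param matrix A `system_matrix` (possibly row-subset by
#'   [select_frequencies()]).
#' @param spectrum A `corrected_spectrum`, or a complex vector on the matrix
#'   frequency grid.
#' @param lambda Relative regularization factor (>= 0).
#' @param iterations Number of full sweeps (default 5).
#' @param nonneg Apply the real/non-negativity projection after each sweep.
#' @return An object of class `recon_volume`: a [voxel_grid()] carrying the
#'   reconstructed concentrations plus `lambda`, `iterations`,
#'   `skipped_rows`.
#' @export
kaczmarz <- function(matrix, spectrum, lambda = 1e-2, iterations = 5,
                     nonneg = TRUE) {
  stopifnot(inherits(matrix, "system_matrix"), lambda >= 0, iterations >= 1)
  u <- if (inherits(spectrum, "corrected_spectrum")) spectrum$spectrum
       else spectrum
  S <- matrix$S
  if (length(u) != nrow(S))
    stop("spectrum length ", length(u), " does not match matrix rows ",
         nrow(S))
  energy <- rowSums(Mod(S)^2)
  skipped <- which(energy == 0)
  active <- which(energy > 0)
  lam_abs <- lambda * mean(energy[active])
  sql <- sqrt(lam_abs)
  c_vec <- complex(real = numeric(ncol(S)))
  v <- complex(real = numeric(nrow(S)))
  for (sweep in seq_len(iterations)) {
    for (i in active) {
      si <- S[i, ]
      alpha <- (u[i] - sum(si * c_vec) - sql * v[i]) / (energy[i] + lam_abs)
      c_vec <- c_vec + alpha * Conj(si)
      v[i] <- v[i] + alpha * sql
    }
    if (nonneg) c_vec <- complex(real = pmax(Re(c_vec), 0))
  }
  vals <- if (nonneg) pmax(Re(c_vec), 0) else Re(c_vec)
  geom <- matrix$grid_geom
  out <- voxel_grid(geom$shape, geom$voxel_mm, geom$origin_mm,
                    array(pmax(vals, 0), dim = geom$shape))
  if (!nonneg) out$values <- array(vals, dim = geom$shape)
  structure(c(out, list(lambda = lambda, iterations = iterations,
                        nonneg = nonneg,
                        skipped_rows = skipped,
                        solution = vals)),
            class = c("recon_volume", "voxel_grid"))
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("Reconstruction (lambda = %g, %d sweeps): ", x$lambda,
              x$iterations))
  NextMethod()
}
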