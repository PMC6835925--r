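#' Threshold and active-contour segmentation of a reconstructed volume
#'
#' Reproduces the evaluation protocol of the phantom study: a cut-off
#' threshold at a fraction of the volume maximum is first applied to the
#' image itself (eliminating most background noise and artifacts), and the
#' cut image is then segmented slice-by-slice along the tube axis with a
#' region-based (piecewise-constant, Chan-Vese type) active contour iterated
#' a fixed number of times. Each iteration reassigns pixels by the
#' two-region data term plus a contrast-scaled length penalty. On clean data
#' the contour converges to the supra-threshold support; its role is to
#' absorb noise speckle and smooth boundaries. The 3D object mask is the
#' stack of the 2D slice masks.
#'
#' @param volume A `recon_volume` or [voxel_grid()] of finite values with a
#'   positive maximum.
#' @param cutoff_fraction Initial threshold as a fraction of the maximum
#'   (default 0.30).
#' @param contour_iterations Active-contour iterations per slice (default
#'   100).
#' @param axis Slicing axis (1 = x, 3 = z), normally the phantom long axis.
#' @return An object of class `segmentation`: logical arrays `object` and
#'   `background` (complement of the object dilated by one voxel), a
#'   `failed` flag with `reason`, and the method settings.
#' @export
segment <- function(volume, cutoff_fraction = 0.30, contour_iterations = 100,
                    axis = 1) {
  stopifnot(inherits(volume, "voxel_grid"), axis %in% c(1, 2, 3))
  vals <- volume$values
  stopifnot(all(is.finite(vals)))
  vmax <- max(vals)
  fail <- function(reason) structure(
    list(object = array(FALSE, dim(vals)),
         background = array(TRUE, dim(vals)),
         failed = TRUE, reason = reason,
         cutoff_fraction = cutoff_fraction,
         contour_iterations = contour_iterations, axis = axis),
    class = "segmentation")
  if (vmax <= 0) return(fail("all-zero volume"))
  init <- vals >= cutoff_fraction * vmax
  if (all(init)) return(fail("no contrast: threshold selects every voxel"))
  if (!any(init)) return(fail("threshold selects no voxel"))
  cut <- vals
  cut[!init] <- 0
  mask <- array(FALSE, dim(vals))
  n_sl <- dim(vals)[axis]
  for (s in seq_len(n_sl)) {
    sl <- slice_array(cut, axis, s)
    m0 <- slice_array(init, axis, s)
    if (!any(m0)) next
    mask <- assign_slice(mask, axis, s,
                         chan_vese_2d(sl, m0, contour_iterations))
  }
  if (!any(mask)) return(fail("active contours removed all voxels"))
  if (all(mask)) return(fail("object mask covers the whole volume"))
  bg <- !dilate3d(mask)
  if (!any(bg)) return(fail("no background voxels remain after dilation"))
  structure(list(object = mask, background = bg, failed = FALSE,
                 reason = NULL, cutoff_fraction = cutoff_fraction,
                 contour_iterations = contour_iterations, axis = axis),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  if (x$failed) cat("Segmentation FAILED:", x$reason, "\n")
  else cat(sprintf("Segmentation: %d object voxels, %d background voxels\n",
                   sum(x$object), sum(x$background)))
  invisible(x)
}

slice_array <- function(a, axis, i) {
  switch(axis, a[i, , ], a[, i, ], a[, , i])
}
assign_slice <- function(a, axis, i, val) {
  switch(axis, a[i, , ] <- val, a[, i, ] <- val, a[, , i] <- val)
  a
}

# Region-based (piecewise-constant) active contour on one 2D slice:
# discrete descent of the two-phase Chan-Vese energy. Each iteration
# recomputes the region means and flips pixels by the sign of
#   (I - c2)^2 - (I - c1)^2 + nu * (c1 - c2)^2 * (1 - 2 * mean3x3(u)),
# i.e. the data term plus a length penalty whose weight scales with the
# squared region contrast (intensity-scale invariant). The penalty is weak
# enough to preserve structures a few pixels across while removing isolated
# misclassified pixels.
chan_vese_2d <- function(img, mask0, iterations, nu = 0.3) {
  u <- mask0
  for (it in seq_len(iterations)) {
    if (!any(u) || all(u)) break
    c1 <- mean(img[u]); c2 <- mean(img[!u])
    if (!is.finite(c1) || !is.finite(c2) || isTRUE(all.equal(c1, c2))) break
    curv <- nu * (c1 - c2)^2 * (1 - 2 * mean3x3(u))
    u_new <- (img - c2)^2 - (img - c1)^2 - curv > 0
    if (identical(u_new, u)) break
    u <- u_new
  }
  u
}

# 3x3 box mean with edge replication.
mean3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  ri <- function(d) pmin(pmax(seq_len(nr) + d, 1), nr)
  ci <- function(d) pmin(pmax(seq_len(nc) + d, 1), nc)
  for (dr in -1:1) for (dc in -1:1)
    acc <- acc + m[ri(dr), ci(dc)]
  acc / 9
}

# 26-neighborhood binary dilation by one voxel.
dilate3d <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  ix <- function(n, s) pmin(pmax(seq_len(n) + s, 1), n)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    out <- out | mask[ix(d[1], dx), ix(d[2], dy), ix(d[3], dz)]
  out
}

#' Signal-to-noise ratio of a segmented reconstruction
#'
#' SNR is the mean signal level of the segmented object divided by the mean
#' signal level of the background, both computed on the pre-threshold
#' intensities. The background mask excludes a one-voxel shell around the
#' object to avoid partial-volume contamination. A zero background mean is
#' flagged as infinite SNR rather than an error.
#'
#' @param volume The reconstructed [voxel_grid()] that was segmented.
#' @param seg A [segment()] result.
#' @return SNR (dimensionless); `Inf` with a warning attribute when the
#'   background mean is zero; `NA` for failed segmentations.
#' @export
snr <- function(volume, seg) {
  stopifnot(inherits(volume, "voxel_grid"), inherits(seg, "segmentation"))
  if (seg$failed) return(NA_real_)
  obj_mean <- mean(volume$values[seg$object])
  bg_mean <- mean(volume$values[seg$background])
  if (bg_mean == 0) {
    out <- Inf
    attr(out, "flag") <- "zero background mean"
    return(out)
  }
  obj_mean / bg_mean
}

#' Volume and iron quantification of a segmented reconstruction
#'
#' The visualized volume is the number of object voxels times the voxel
#' volume; the iron amount is the integral of the concentration map over the
#' object mask. Percent deviations are reported against the known phantom
#' references.
#'
#' @param volume Reconstructed [voxel_grid()] (mmol Fe/l).
#' @param seg A [segment()] result.
#' @param reference_volume_ul Known fill volume in uL (optional).
#' @param reference_iron_umol Known iron amount in umol (optional).
#' @return A list of class `quant_report`: `volume_ul`, `iron_umol`,
#'   `volume_deviation_percent`, `iron_deviation_percent`, `flagged`.
#' @export
volume_and_iron <- function(volume, seg, reference_volume_ul = NA,
                            reference_iron_umol = NA) {
  stopifnot(inherits(volume, "voxel_grid"), inherits(seg, "segmentation"))
  voxel_ul <- prod(volume$voxel_mm)
  if (seg$failed || !any(seg$object)) {
    return(structure(list(volume_ul = 0, iron_umol = 0,
                          volume_deviation_percent = NA_real_,
                          iron_deviation_percent = NA_real_,
                          flagged = TRUE,
                          reason = if (seg$failed) seg$reason else "empty mask"),
                     class = "quant_report"))
  }
  vol_ul <- sum(seg$object) * voxel_ul
  iron <- sum(volume$values[seg$object]) * voxel_ul * 1e-3
  structure(list(
    volume_ul = vol_ul,
    iron_umol = iron,
    volume_deviation_percent =
      if (is.na(reference_volume_ul)) NA_real_ else
        100 * (vol_ul / reference_volume_ul - 1),
    iron_deviation_percent =
      if (is.na(reference_iron_umol)) NA_real_ else
        100 * (iron / reference_iron_umol - 1),
    flagged = FALSE, reason = NULL),
    class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("Quantification: volume %.3g uL, iron %.3g umol",
              x$volume_ul, x$iron_umol))
  if (!is.na(x$volume_deviation_percent))
    cat(sprintf(" (volume %+.1f%%, iron %+.1f%% vs reference)",
                x$volume_deviation_percent, x$iron_deviation_percent))
  if (x$flagged) cat("  [FLAGGED: ", x$reason, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' SNR-versus-regularization sweep
#'
#' Reconstructs the same spectrum at a grid of relative regularization
#' factors (default the seven decades 10^0 ... 10^-6), segments and scores
#' each reconstruction, and reports the SNR-maximizing lambda. Ties are
#' broken toward the larger lambda (stronger regularization); per-lambda
#' segmentation failures are recorded as missing rather than aborting the
#' sweep.
#'
#' @param matrix A `system_matrix`.
#' @param spectrum Corrected spectrum (see [kaczmarz()]).
#' @param lambdas Regularization factors (>= 2 values).
#' @param iterations,nonneg Passed to [kaczmarz()].
#' @param cutoff_fraction,contour_iterations,axis Passed to [segment()].
#' @param reference_volume_ul,reference_iron_umol Passed to
#'   [volume_and_iron()].
#' @return A list of class `lambda_sweep`: `table` (data.frame lambda, snr,
#'   volume_ul, iron_umol, failed), `best_lambda`, and `volumes` (the
#'   per-lambda reconstructions).
#' @export
lambda_sweep <- function(matrix, spectrum, lambdas = 10^(0:-6),
                         iterations = 5, nonneg = TRUE,
                         cutoff_fraction = 0.30, contour_iterations = 100,
                         axis = 1, reference_volume_ul = NA,
                         reference_iron_umol = NA) {
  stopifnot(length(lambdas) >= 2)
  lambdas <- sort(lambdas, decreasing = TRUE)
  rows <- vector("list", length(lambdas))
  vols <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    vol <- kaczmarz(matrix, spectrum, lambda = lambdas[i],
                    iterations = iterations, nonneg = nonneg)
    sg <- segment(vol, cutoff_fraction, contour_iterations, axis)
    qq <- volume_and_iron(vol, sg, reference_volume_ul, reference_iron_umol)
    rows[[i]] <- data.frame(lambda = lambdas[i],
                            snr = as.numeric(snr(vol, sg)),
                            volume_ul = qq$volume_ul,
                            iron_umol = qq$iron_umol,
                            failed = sg$failed)
    vols[[i]] <- vol
  }
  tab <- do.call(rbind, rows)
  valid <- which(!tab$failed & !is.na(tab$snr))
  if (!length(valid)) stop("segmentation failed at every lambda")
  # max SNR; ties toward larger lambda (table is sorted descending in lambda)
  best <- valid[which.max(tab$snr[valid])]
  structure(list(table = tab, best_lambda = tab$lambda[best],
                 volumes = vols),
            class = "lambda_sweep")
}

#' @export
print.lambda_sweep <- function(x, ...) {
  print(x$table)
  cat("best lambda:", format(x$best_lambda), "\n")
  invisible(x)
}

#' Dual-tube separability and shadowing metrics
#'
#' Quantifies how well two adjacent tubes are resolved: separability is the
#' presence of two connected components in the 50%-threshold maximum
#' intensity projection, and the shadowing ratio is the peak intensity in the
#' half-volume of the tube with the lower iron amount divided by the peak in
#' the half-volume of the higher-iron tube (1 for symmetric tubes; it drops
#' as the iron-amount ratio grows, the shadowing effect). The iron-amount
#' ratio of the assembly is computed from the phantom specification.
#'
#' @param volume Reconstructed [voxel_grid()].
#' @param phantom The generating dual-tube [phantom_spec()].
#' @param threshold_fraction MIP threshold fraction (default 0.50).
#' @return A list of class `dual_tube_report`: `separable`, `n_components`,
#'   `shadowing_ratio`, `iron_ratio`, per-tube peaks.
#' @export
dual_tube_metrics <- function(volume, phantom, threshold_fraction = 0.50) {
  stopifnot(inherits(volume, "voxel_grid"), inherits(phantom, "phantom_spec"))
  if (phantom$assembly != "dual")
    stop("dual_tube_metrics requires a dual-tube phantom")
  tubes <- phantom$tubes
  iron <- tubes$fill_volume_ul * tubes$concentration_mmol_l
  lo <- which.min(iron); hi <- which.max(iron)
  if (lo == hi) { lo <- 1; hi <- 2 }
  # split the volume across the mid-plane between the two tube centers (y)
  ys <- grid_axis_coords(volume, 2)
  mid <- mean(tubes$offset_mm)
  side <- function(i) {
    sel <- if (tubes$offset_mm[i] < mid) ys < mid else ys >= mid
    max(volume$values[, sel, , drop = FALSE])
  }
  peak_lo <- side(lo); peak_hi <- side(hi)
  # separability on the thresholded MIP across the projection axis
  proj_axis <- if (tubes$axis[1] == "x") 3 else 1
  mip <- mip_render(volume, threshold_fraction, axis = proj_axis)
  labels <- EBImage::bwlabel(mip > 0)
  ncomp <- max(labels)
  structure(list(separable = ncomp >= 2, n_components = ncomp,
                 shadowing_ratio = if (peak_hi > 0) peak_lo / peak_hi else
                   NA_real_,
                 iron_ratio = max(iron) / min(iron),
                 peak_low_iron = peak_lo, peak_high_iron = peak_hi),
            class = "dual_tube_report")
}

#' @export
print.dual_tube_report <- function(x, ...) {
  cat(sprintf("Dual-tube report: iron ratio %.3g:1, %sseparable (%d components), shadowing ratio %.3f\n",
              x$iron_ratio, if (x$separable) "" else "NOT ",
              x$n_components, x$shadowing_ratio))
  invisible(x)
}

#' Thresholded maximum intensity projection
#'
#' Zeroes values below a fraction of the volume maximum and takes the
#' maximum along one axis, the standard rendering of reconstructed phantom
#' volumes. Optionally upscales the projection by bilinear interpolation for
#' display.
#'
#' @param volume A [voxel_grid()].
#' @param threshold_fraction Fraction of the maximum below which values are
#'   zeroed (0 for a plain MIP).
#' @param axis Projection axis (1, 2 or 3).
#' @param upscale Integer display upscaling factor (1 = none).
#' @return A numeric matrix (the two remaining axes in order).
#' @export
mip_render <- function(volume, threshold_fraction = 0.50, axis = 3,
                       upscale = 1) {
  stopifnot(inherits(volume, "voxel_grid"), axis %in% 1:3,
            threshold_fraction >= 0, upscale >= 1)
  v <- volume$values
  if (threshold_fraction > 0 && max(v) > 0)
    v[v < threshold_fraction * max(v)] <- 0
  mip <- apply(v, setdiff(1:3, axis), max)
  if (upscale > 1)
    mip <- EBImage::resize(mip, w = nrow(mip) * upscale,
                           h = ncol(mip) * upscale)
  mip
}
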