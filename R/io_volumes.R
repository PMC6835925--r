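#' Write and read concentration volumes as NIfTI
#'
#' Volumes are exchanged as NIfTI-1 images with the voxel size (mm) carried
#' in the header; values are concentrations in mmol Fe/l.
#'
#' @param grid A [voxel_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti`: the path, invisibly. `read_volume_nifti`:
#'   a [voxel_grid()].
#' @export
write_volume_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  vals <- array(as.numeric(img), dim = dim(img))
  voxel_grid(dim(img), vox, values = pmax(vals, 0))
}

#' Save and load scanner bundles
#'
#' System matrices and raw signals are serialized as single RDS container
#' files with their named components (`S`/`spectra`, `rows`, configuration
#' and provenance fields) intact.
#'
#' @param object A `system_matrix` or `raw_signal`.
#' @param path Output `.rds` path.
#' @export
save_bundle <- function(object, path) {
  stopifnot(inherits(object, c("system_matrix", "raw_signal")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) readRDS(path)
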