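#' Masked grayscale volume
#'
#' An `roi_volume` bundles a 3D grayscale intensity array with an aligned
#' binary mask and per-axis voxel spacing. It is the unit of radiomics
#' feature extraction: all texture and first-order features are computed
#' over the voxels where `mask` is `TRUE`. A video clip is represented as a
#' stacked volume with frames along the third axis.
#'
#' @param intensities 3D numeric array of grayscale values.
#' @param mask 3D logical (or 0/1) array with the same extents; must select
#'   at least 2 voxels.
#' @param spacing numeric length-3 voxel size per axis (arbitrary units).
#'
#' @return An object of class `roi_volume`: a list with elements
#'   `intensities`, `mask` and `spacing`.
#' @export
#'
#' @examples
#' vol <- roi_volume(array(rnorm(64), c(4, 4, 4)),
#'                   array(TRUE, c(4, 4, 4)))
#' dim(vol$intensities)
roi_volume <- function(intensities, mask, spacing = c(1, 1, 1)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3D array.")
  }
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(intensities))) {
    abort("`mask` extents must match `intensities`.")
  }
  if (anyNA(mask)) abort("`mask` must not contain missing values.")
  if (sum(mask) < 2L) abort("`mask` must select at least 2 voxels.")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive voxel sizes.")
  }
  structure(
    list(intensities = intensities, mask = mask, spacing = as.numeric(spacing)),
    class = "roi_volume"
  )
}

#' @export
print.roi_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<roi_volume> %d x %d x %d, %d masked voxels, spacing %s\n",
              d[1], d[2], d[3], sum(x$mask),
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Read and write ROI volumes as NIfTI image/mask pairs
#'
#' The volume is stored as two NIfTI files: `<stem>.nii.gz` for the
#' intensities and `<stem>_mask.nii.gz` for the binary mask. Voxel spacing
#' is carried in the NIfTI header.
#'
#' @param volume an [roi_volume()].
#' @param stem file path stem (without extension).
#' @return `write_roi_volume()` returns `stem` invisibly;
#'   `read_roi_volume()` returns an [roi_volume()].
#' @export
write_roi_volume <- function(volume, stem) {
  stopifnot(inherits(volume, "roi_volume"))
  img <- RNifti::asNifti(volume$intensities, pixdim = volume$spacing)
  msk <- RNifti::asNifti(array(as.numeric(volume$mask), dim(volume$mask)),
                         pixdim = volume$spacing)
  RNifti::writeNifti(img, paste0(stem, ".nii.gz"))
  RNifti::writeNifti(msk, paste0(stem, "_mask.nii.gz"))
  invisible(stem)
}

#' @rdname write_roi_volume
#' @export
read_roi_volume <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  msk <- RNifti::readNifti(paste0(stem, "_mask.nii.gz"))
  spacing <- RNifti::pixdim(img)[1:3]
  roi_volume(array(as.numeric(img), dim(img)),
             array(as.numeric(msk) > 0.5, dim(msk)),
             spacing = spacing)
}
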