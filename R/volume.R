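#' Construct a 3D intensity volume with an aligned binary ROI mask
#'
#' The basic unit consumed by every imaging operation: a 3D array of
#' intensities (rows x columns x slices, slices being the axial direction),
#' the physical voxel spacing in millimetres, and a binary region-of-interest
#' mask of identical shape (the contoured gross tumour volume in the clinical
#' setting).
#'
#' @param intensities 3D numeric array.
#' @param spacing_mm length-3 positive numeric: (row, column, slice) spacing
#'   in millimetres.
#' @param mask 3D logical (or 0/1) array of the same shape as `intensities`,
#'   with at least one voxel set.
#' @return An object of class `volume_with_mask`.
#' @export
volume_with_mask <- function(intensities, spacing_mm, mask) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array", call. = FALSE)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive values", call. = FALSE)
  if (!identical(dim(mask), dim(intensities)))
    stop("mask shape must equal intensity shape", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask must be binary with no missing values", call. = FALSE)
  if (!any(mask)) stop("mask must contain at least one voxel", call. = FALSE)
  structure(
    list(intensities = intensities, spacing_mm = as.numeric(spacing_mm), mask = mask),
    class = "volume_with_mask"
  )
}

#' @export
print.volume_with_mask <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<volume_with_mask> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm, %d ROI voxels\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    sum(x$mask)
  ))
  invisible(x)
}

#' Extract the ROI intensity values of a volume
#'
#' @param v A `volume_with_mask`.
#' @return Numeric vector of intensities at masked voxels.
#' @export
roi_values <- function(v) {
  stopifnot(inherits(v, "volume_with_mask"))
  v$intensities[v$mask]
}

#' Read a volume and ROI mask from NIfTI files
#'
#' Voxel spacing is taken from the image header; the mask is binarised at 0.5.
#'
#' @param image_path,mask_path Paths to NIfTI volumes of identical shape.
#' @return A `volume_with_mask`.
#' @export
read_volume_nifti <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  volume_with_mask(array(as.numeric(img), dim = dim(img)), spacing,
                   array(as.numeric(msk) >= 0.5, dim = dim(msk)))
}

#' Write a volume and its mask as NIfTI files
#'
#' @param v A `volume_with_mask`.
#' @param image_path,mask_path Output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the image path.
#' @export
write_volume_nifti <- function(v, image_path, mask_path) {
  stopifnot(inherits(v, "volume_with_mask"))
  img <- RNifti::asNifti(v$intensities)
  RNifti::pixdim(img) <- v$spacing_mm
  RNifti::writeNifti(img, image_path)
  msk <- RNifti::asNifti(array(as.numeric(v$mask), dim = dim(v$mask)))
  RNifti::pixdim(msk) <- v$spacing_mm
  RNifti::writeNifti(msk, mask_path)
  invisible(image_path)
}
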