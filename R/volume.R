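#' CT volume container
#'
#' A minimal carrier for a 3D CT image: a numeric array of intensities in
#' Hounsfield units (HU) plus the voxel spacing in millimetres. The array is
#' indexed `[z, y, x]` (1-based, axial plane = fixed `z`), and `spacing`
#' follows the same `(z, y, x)` order.
#'
#' @param data 3D numeric array of HU values, indexed `[z, y, x]`.
#' @param spacing numeric length-3 vector of voxel spacing in mm, `(z, y, x)`.
#' @return An object of class `ct_volume` with elements `data` and `spacing`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive reals (mm)")
  structure(list(data = data, spacing = spacing), class = "ct_volume")
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

as_ct_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "ct_volume")) return(x)
  ct_volume(x, spacing)
}

#' Write a CT volume or mask to NIfTI
#'
#' Volumes are stored as signed 16-bit HU (rounded), masks as unsigned 8-bit
#' \{0,1\}. The internal `(z, y, x)` array is permuted to the NIfTI `(x, y, z)`
#' convention on disk.
#'
#' @param vol a [ct_volume()], or for `write_mask` a binary array.
#' @param path output path, conventionally ending in `.nii.gz`.
#' @param spacing voxel spacing (z, y, x) in mm, used for `write_mask`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  arr <- aperm(round(vol$data), c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(vol, path, spacing = c(1, 1, 1)) {
  arr <- if (inherits(vol, "ct_volume")) vol$data else vol
  spacing <- if (inherits(vol, "ct_volume")) vol$spacing else spacing
  stopifnot(all(arr %in% c(0, 1)))
  img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a CT volume or mask from NIfTI
#'
#' @param path NIfTI file path.
#' @return For `read_volume` a [ct_volume()]; for `read_mask` an integer
#'   \{0,1\} array indexed `(z, y, x)`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
  ct_volume(arr, rev(sp[seq_len(3)]))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- aperm(array(as.integer(img != 0), dim(img)), c(3, 2, 1))
  arr
}
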