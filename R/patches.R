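#' Triplanar multiscale patch specification
#'
#' Defines the sampling geometry of the segmentation classifier's input: an
#' odd in-plane patch edge (so a centre voxel exists) and exactly two
#' in-plane sampling factors, a fine and a coarse scale (coarse > fine). At
#' scale `s`, pixel `j` of a patch row samples the volume `s * (j - centre)`
#' voxels from the centre, with linear interpolation for non-integer
#' positions and mirror reflection beyond the grid.
#'
#' @param patch_edge odd positive integer, patch edge length in pixels.
#' @param scales two positive in-plane sampling factors, fine then coarse.
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(patch_edge = 25L, scales = c(1, 3)) {
  patch_edge <- as.integer(patch_edge)
  if (is.na(patch_edge) || patch_edge < 1 || patch_edge %% 2L == 0L)
    stop("`patch_edge` must be an odd positive integer")
  scales <- as.numeric(scales)
  if (length(scales) != 2 || any(scales <= 0))
    stop("`scales` must be exactly two positive sampling factors")
  scales <- sort(scales)
  if (scales[1] == scales[2]) stop("fine and coarse scales must differ")
  structure(list(patch_edge = patch_edge, scales = scales),
            class = "patch_spec")
}

# (fixed, row, col) array dimension per anatomical plane, (z, y, x) indexing.
plane_axes <- list(axial    = c(1L, 2L, 3L),
                   coronal  = c(2L, 1L, 3L),
                   sagittal = c(3L, 1L, 2L))

# Gather one plane's patches for a batch of centre voxels.
# vol: (z,y,x) array; voxels: m x 3 integer matrix; offs: real offsets.
# Returns (p, p, m) with rows/cols per `plane_axes`.
extract_plane_batch <- function(vol, voxels, plane, offs) {
  d <- dim(vol)
  mult <- c(1, d[1], d[1] * d[2])
  ax <- plane_axes[[plane]]
  p <- length(offs)
  m <- nrow(voxels)
  base <- 1 + (voxels[, ax[1]] - 1) * mult[ax[1]]

  expand_rows <- function(Arow) {        # (m x p) row term  -> (p, p, m)
    aperm(array(t(Arow), c(p, m, p)), c(1, 3, 2))
  }
  expand_cols <- function(Bcol) {        # (m x p) col term  -> (p, p, m)
    aperm(array(t(Bcol), c(p, m, p)), c(3, 1, 2))
  }

  integer_offs <- all(abs(offs - round(offs)) < 1e-9)
  if (integer_offs) {
    offs <- round(offs)
    rows <- outer(voxels[, ax[2]], offs, "+")
    cols <- outer(voxels[, ax[3]], offs, "+")
    A <- base + (matrix(reflect_index(rows, d[ax[2]]), m, p) - 1) * mult[ax[2]]
    B <- (matrix(reflect_index(cols, d[ax[3]]), m, p) - 1) * mult[ax[3]]
    out <- vol[expand_rows(A) + expand_cols(B)]
    return(array(out, c(p, p, m)))
  }
  # bilinear interpolation between the four surrounding grid lines
  rows <- outer(voxels[, ax[2]], offs, "+")
  cols <- outer(voxels[, ax[3]], offs, "+")
  r0 <- floor(rows); fr <- rows - r0
  c0 <- floor(cols); fc <- cols - c0
  ridx <- function(ri) base + (matrix(reflect_index(ri, d[ax[2]]), m, p) - 1) * mult[ax[2]]
  cidx <- function(ci) (matrix(reflect_index(ci, d[ax[3]]), m, p) - 1) * mult[ax[3]]
  A0 <- expand_rows(ridx(r0));      A1 <- expand_rows(ridx(r0 + 1))
  B0 <- expand_cols(cidx(c0));      B1 <- expand_cols(cidx(c0 + 1))
  WR1 <- expand_rows(fr);           WC1 <- expand_cols(fc)
  out <- (1 - WR1) * (1 - WC1) * vol[A0 + B0] +
         WR1       * (1 - WC1) * vol[A1 + B0] +
         (1 - WR1) * WC1       * vol[A0 + B1] +
         WR1       * WC1       * vol[A1 + B1]
  array(out, c(p, p, m))
}

# Batch triplanar extraction at one scale: (p, p, 3, m), channels in the
# order axial, coronal, sagittal.
extract_patch_batch <- function(vol, voxels, edge, scale) {
  h <- (edge - 1L) / 2L
  offs <- seq(-h, h) * scale
  planes <- lapply(names(plane_axes), function(pl)
    extract_plane_batch(vol, voxels, pl, offs))
  out <- array(0, c(edge, edge, 3, nrow(voxels)))
  for (ch in 1:3) out[, , ch, ] <- planes[[ch]]
  out
}

#' Extract the six triplanar multiscale patches around one voxel
#'
#' Returns the axial, coronal and sagittal in-plane patches centred on the
#' target voxel at both the fine and coarse scale. The centre pixel of every
#' fine-scale patch equals the volume intensity at the voxel. Samples
#' falling outside the grid are mirror-reflected.
#'
#' @param volume a [ct_volume()] or 3D array indexed `(z, y, x)`.
#' @param voxel integer length-3 voxel index `(z, y, x)`, 1-based, inside
#'   the grid.
#' @param spec a [patch_spec()].
#' @return A named list of six `patch_edge x patch_edge` matrices:
#'   `axial_fine`, `coronal_fine`, `sagittal_fine`, `axial_coarse`,
#'   `coronal_coarse`, `sagittal_coarse`.
#' @export
extract_triplanar_patches <- function(volume, voxel, spec = patch_spec()) {
  vol <- if (inherits(volume, "ct_volume")) volume$data else volume
  d <- dim(vol)
  voxel <- as.integer(voxel)
  if (length(voxel) != 3 || any(voxel < 1) || any(voxel > d))
    stop(sprintf("voxel index (%s) outside the %s grid",
                 paste(voxel, collapse = ", "), paste(d, collapse = "x")))
  vx <- matrix(voxel, nrow = 1)
  fine <- extract_patch_batch(vol, vx, spec$patch_edge, spec$scales[1])
  coarse <- extract_patch_batch(vol, vx, spec$patch_edge, spec$scales[2])
  out <- list(axial_fine = fine[, , 1, 1], coronal_fine = fine[, , 2, 1],
              sagittal_fine = fine[, , 3, 1],
              axial_coarse = coarse[, , 1, 1], coronal_coarse = coarse[, , 2, 1],
              sagittal_coarse = coarse[, , 3, 1])
  attr(out, "patch_spec") <- spec
  out
}
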