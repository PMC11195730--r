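#' Voxel volumes
#'
#' A `voxel_volume` is a 3-D numeric array of Hounsfield units (HU) together
#' with a 4x4 voxel-to-physical affine. Physical coordinates are in mm and are
#' obtained from 0-based voxel indices, following the NIfTI convention:
#' `world = affine %*% c(i, j, k, 1)` for the voxel stored at
#' `array[i + 1, j + 1, k + 1]`.
#'
#' @param data numeric 3-D array of HU values.
#' @param affine 4x4 voxel-to-physical matrix; defaults to identity spacing
#'   given by `spacing`.
#' @param spacing length-3 voxel size in mm, used only when `affine` is NULL.
#' @return A `voxel_volume` object (array with an `affine` attribute).
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' voxel_size_mm3(v)
#' @export
voxel_volume <- function(data, affine = NULL, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array", call. = FALSE)
  if (is.null(affine)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0))
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4", call. = FALSE)
  structure(data, affine = affine, class = c("voxel_volume", class(data)))
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, voxel volume %.4g mm^3, HU range [%.4g, %.4g]\n",
    d[1], d[2], d[3], voxel_size_mm3(x), min(x), max(x)
  ))
  invisible(x)
}

vol_affine <- function(volume) {
  a <- attr(volume, "affine")
  if (is.null(a)) diag(4) else a
}

#' Physical volume of one voxel
#'
#' @param volume a `voxel_volume` (or any array carrying an `affine` attribute).
#' @return Voxel volume in mm^3 (absolute determinant of the affine's 3x3 block).
#' @export
voxel_size_mm3 <- function(volume) {
  abs(det(vol_affine(volume)[1:3, 1:3]))
}

#' Physical coordinates of voxels
#'
#' Maps (0-based) voxel indices through the affine to physical mm.
#'
#' @param volume a `voxel_volume`.
#' @param idx integer matrix with three columns of 0-based voxel indices;
#'   when NULL, all voxels in column-major storage order.
#' @return n x 3 matrix of physical coordinates in mm.
#' @export
voxel_coords <- function(volume, idx = NULL) {
  d <- dim(volume)
  if (is.null(idx)) {
    idx <- as.matrix(expand.grid(
      i = seq_len(d[1]) - 1L, j = seq_len(d[2]) - 1L, k = seq_len(d[3]) - 1L
    ))
  }
  a <- vol_affine(volume)
  xyz <- cbind(idx, 1) %*% t(a)
  xyz[, 1:3, drop = FALSE]
}

# 0-based index matrix of TRUE voxels of a logical array, column-major order.
mask_indices <- function(mask) {
  which(mask, arr.ind = TRUE) - 1L
}

check_aligned <- function(volume, mask, what = "mask") {
  if (!identical(dim(volume), dim(mask))) {
    stop(sprintf("%s dimensions %s do not match volume dimensions %s",
                 what, paste(dim(mask), collapse = "x"),
                 paste(dim(volume), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers over RNifti that carry the affine into and out of
#' [voxel_volume()].
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a `voxel_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_volume(unclass(as.array(img)), affine = RNifti::xform(img))
}

#' @rdname read_volume
#' @param volume a `voxel_volume` to write.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(unclass(volume))
  RNifti::sform(img) <- structure(vol_affine(volume), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
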