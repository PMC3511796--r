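#' 4D BOLD time-series image
#'
#' Container for one subject's functional run: an X x Y x Z x T array, the
#' voxel-to-world affine (mm), and the repetition time (seconds).
#'
#' @param data numeric 4D array (X x Y x Z x T).
#' @param affine 4x4 voxel-to-world transform in mm.  Voxel indices are
#'   0-based when mapped through the affine, following the NIfTI convention.
#' @param tr_s repetition time in seconds.
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, affine, tr_s) {
  if (length(dim(data)) != 4L)
    stopf("`data` must be a 4D array, got %d dims", length(dim(data)))
  if (dim(data)[4] < 2L)
    stopf("a BOLD run needs at least 2 volumes, got %d", dim(data)[4])
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stopf("`affine` must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stopf("`affine` must be invertible")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stopf("`tr_s` must be a positive scalar (seconds)")
  structure(list(data = data, affine = affine, tr_s = as.numeric(tr_s)),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  cat(sprintf("  voxel size: %s mm\n",
              paste(signif(voxel_sizes(x$affine), 4), collapse = " x ")))
  invisible(x)
}

#' Binary brain mask on a voxel grid
#'
#' @param data logical 3D array; `TRUE` marks in-mask voxels.
#' @param affine 4x4 voxel-to-world transform shared with the images the
#'   mask applies to.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data, affine) {
  if (length(dim(data)) != 3L) stopf("mask `data` must be a 3D array")
  data <- array(as.logical(data), dim(data))
  if (!any(data)) stopf("mask contains no TRUE voxel")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stopf("`affine` must be a 4x4 matrix")
  structure(list(data = data, affine = affine), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d in-mask voxels\n",
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

# Per-axis voxel sizes (mm) from an affine.
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# Map 1-based voxel array indices (matrix, rows = voxels) to world mm.
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  h <- cbind(ijk - 1, 1)             # NIfTI affines index voxels from 0
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

same_grid <- function(a_dim, b_dim) length(a_dim) >= 3L &&
  length(b_dim) >= 3L && all(a_dim[1:3] == b_dim[1:3])

# xform() attaches attributes; keep a bare 4x4 matrix.
bare_affine <- function(im) {
  m <- RNifti::xform(im)
  matrix(as.numeric(m), 4L, 4L)
}

# niftiImage arrays carry header attributes; keep a bare numeric array.
bare_array <- function(im) {
  a <- as.array(im)
  array(as.numeric(a), dim(a))
}

#' Read a 4D NIfTI file as a `bold4d`
#'
#' The repetition time is taken from the NIfTI header's time-step slot
#' (pixdim\[4\]) unless overridden.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param tr_s optional repetition time override in seconds.
#' @return A [bold4d()] object.
#' @export
read_bold <- function(path, tr_s = NULL) {
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 4L) stopf("%s is not a 4D image", path)
  pd <- RNifti::pixdim(im)
  tr <- tr_s %||% (if (length(pd) >= 4L && pd[4] > 0) pd[4] else
    stopf("%s carries no time step in its header; pass `tr_s`", path))
  bold4d(bare_array(im), bare_affine(im), tr)
}

#' Write a `bold4d` to a NIfTI file
#'
#' @param bold a [bold4d()] object.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_bold <- function(bold, path) {
  im <- RNifti::asNifti(bold$data)
  RNifti::qform(im) <- structure(bold$affine, code = 2L)
  RNifti::sform(im) <- structure(bold$affine, code = 2L)
  RNifti::pixdim(im) <- c(voxel_sizes(bold$affine), bold$tr_s)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a 3D NIfTI file as a `brain_mask`
#'
#' Voxels with value > 0.5 are in-mask.
#'
#' @param path NIfTI file.
#' @return A [brain_mask()] object.
#' @export
read_mask <- function(path) {
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L) stopf("%s is not a 3D mask image", path)
  brain_mask(a > 0.5, bare_affine(im))
}

#' Write a `brain_mask` to a NIfTI file
#'
#' @param mask a [brain_mask()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  im <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::qform(im) <- structure(mask$affine, code = 2L)
  RNifti::sform(im) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}
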