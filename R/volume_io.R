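#' @importFrom stats sd cor quantile rnorm runif rbinom binom.test
#' @importFrom utils write.table read.table head
NULL

#' Volume grid geometry
#'
#' A `volume_grid` records the spatial geometry of a volumetric image:
#' the number of voxels along each axis, the voxel size in mm, and the
#' 4x4 affine mapping zero-based voxel indices to MNI mm coordinates
#' (NIfTI sform convention).
#'
#' @param dims integer triple, voxels per axis (all >= 1).
#' @param voxel_size mm triple (all > 0). Defaults to the column norms of
#'   `affine` when an affine is given.
#' @param affine 4x4 invertible matrix mapping zero-based voxel index
#'   `(i, j, k, 1)` to mm coordinates. Defaults to a diagonal scaling by
#'   `voxel_size` centred so the grid midpoint maps near the origin.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size = NULL, affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be three integers >= 1")
  if (is.null(affine)) {
    if (is.null(voxel_size)) voxel_size <- c(3, 3, 3)
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dims - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  if (is.null(voxel_size))
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  structure(list(dims = dims, voxel_size = as.numeric(voxel_size),
                 affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$dims, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' In-brain voxel mask
#'
#' Restricts all frame-wise computation to `m` in-brain voxels. The fixed
#' voxel order used to flatten volumes into vectors is the column-major
#' (x fastest, then y, then z) order of the included voxels, i.e. NIfTI
#' serialization order; it is identical across calls and sessions.
#'
#' @param grid a [volume_grid()].
#' @param include logical 3D array of the grid's dimensions.
#' @return An object of class `brain_mask` with fields `grid`, `include`,
#'   `m` (number of included voxels) and `idx` (linear indices, the fixed
#'   voxel order).
#' @export
brain_mask <- function(grid, include) {
  stopifnot(inherits(grid, "volume_grid"))
  include <- array(as.logical(include), dim = dim(include))
  if (!identical(dim(include), as.integer(grid$dims)))
    stop("mask shape does not match grid dims")
  idx <- which(include)
  if (length(idx) == 0L) stop("mask includes no voxels")
  structure(list(grid = grid, include = include,
                 m = length(idx), idx = idx),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("brain_mask:", x$m, "of", prod(x$grid$dims), "voxels included\n")
  invisible(x)
}

#' Fallback mask by intensity thresholding
#'
#' Builds an in-brain mask from the data itself when no template mask is
#' supplied: voxels whose temporal-mean intensity exceeds `fraction` of
#' the robust (98th percentile) maximum are included.
#'
#' @param data 4D array (x, y, z, time).
#' @param grid a [volume_grid()].
#' @param fraction threshold as a fraction of the robust maximum.
#' @return A [brain_mask()].
#' @export
mask_from_mean <- function(data, grid, fraction = 0.25) {
  stopifnot(length(dim(data)) == 4L)
  mean_img <- apply(data, 1:3, mean)
  robust_max <- quantile(mean_img, 0.98, names = FALSE)
  brain_mask(grid, mean_img > fraction * robust_max)
}

#' Read a 3D or 4D NIfTI image
#'
#' @param path path to a `.nii` or `.nii.gz` file with 3 or 4 dimensions.
#' @return A list with `grid` (a [volume_grid()]) and `data` (a 4D array;
#'   3D input is promoted to a time axis of length 1).
#' @export
load_4d <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 3L || length(d) > 4L)
    stop("expected a 3D or 4D image, got ", length(d), " dimensions")
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  attributes(affine) <- list(dim = c(4L, 4L))
  vox <- RNifti::pixdim(img)[1:3]
  if (any(vox <= 0)) vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  grid <- volume_grid(d[1:3], voxel_size = vox, affine = affine)
  data <- array(as.numeric(img), dim = c(d[1:3], if (length(d) == 4L) d[4L] else 1L))
  list(grid = grid, data = data)
}

#' Write a 3D or 4D array as NIfTI
#'
#' @param data 3D or 4D numeric array.
#' @param grid a [volume_grid()]; its affine is written as the sform.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_4d <- function(data, grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Flatten a 4D series into a frames-by-voxels matrix
#'
#' Row j holds the in-mask values of frame j in the mask's fixed voxel
#' order; the mapping is inverted by [volume_from_vector()].
#'
#' @param data 4D array whose spatial dims equal the mask grid dims.
#' @param mask a [brain_mask()].
#' @param sessions optional [session_table()] carried along for bookkeeping.
#' @return A `frame_matrix`: list with `values` (n x m matrix), `mask`,
#'   `sessions`.
#' @export
frames_from_4d <- function(data, mask, sessions = NULL) {
  stopifnot(inherits(mask, "brain_mask"))
  d <- dim(data)
  if (length(d) == 3L) { dim(data) <- c(d, 1L); d <- dim(data) }
  if (length(d) != 4L || !identical(as.integer(d[1:3]), mask$grid$dims))
    stop("data spatial dims do not match mask grid")
  n <- d[4L]
  flat <- matrix(data, nrow = prod(d[1:3]), ncol = n)
  values <- t(flat[mask$idx, , drop = FALSE])
  frame_matrix(values, mask, sessions)
}

#' Construct a frame matrix
#'
#' @param values n x m numeric matrix, one row per time frame, one column
#'   per in-mask voxel in the mask's fixed order.
#' @param mask a [brain_mask()] with `m` columns' worth of voxels.
#' @param sessions optional [session_table()].
#' @return An object of class `frame_matrix`.
#' @export
frame_matrix <- function(values, mask, sessions = NULL) {
  values <- as.matrix(values)
  stopifnot(inherits(mask, "brain_mask"))
  if (ncol(values) != mask$m)
    stop("frame matrix has ", ncol(values), " columns but mask has ",
         mask$m, " voxels")
  if (nrow(values) < 1L) stop("need at least one frame")
  if (!is.null(sessions)) validate_sessions(sessions, nrow(values))
  structure(list(values = values, mask = mask, sessions = sessions),
            class = "frame_matrix")
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat("frame_matrix:", nrow(x$values), "frames x", ncol(x$values), "voxels\n")
  invisible(x)
}

#' Place a voxel vector back into a 3D volume
#'
#' The inverse of one row of [frames_from_4d()]: values go to the included
#' voxels in the fixed order, excluded voxels are filled with 0.
#'
#' @param vector numeric vector of length `mask$m`.
#' @param mask a [brain_mask()].
#' @param fill value for excluded voxels (default 0, the background
#'   convention of statistic maps).
#' @return 3D array of the grid's dimensions.
#' @export
volume_from_vector <- function(vector, mask, fill = 0) {
  stopifnot(inherits(mask, "brain_mask"))
  if (length(vector) != mask$m)
    stop("vector length ", length(vector), " != mask voxel count ", mask$m)
  vol <- array(fill, dim = mask$grid$dims)
  vol[mask$idx] <- vector
  vol
}

#' Convert between MNI mm coordinates and voxel indices
#'
#' `mni_to_voxel` applies the inverse affine and rounds to the nearest
#' voxel, ties rounded away from zero; `voxel_to_mni` applies the affine.
#' Voxel indices are 1-based on the R side (the affine itself follows the
#' 0-based NIfTI convention).
#'
#' @param coord MNI mm triple.
#' @param grid a [volume_grid()].
#' @return `mni_to_voxel`: integer triple of 1-based voxel indices;
#'   `voxel_to_mni`: mm triple.
#' @export
mni_to_voxel <- function(coord, grid) {
  stopifnot(inherits(grid, "volume_grid"), length(coord) == 3L)
  v0 <- solve(grid$affine, c(coord, 1))[1:3]
  idx0 <- round_half_away(v0)
  if (any(idx0 < 0L) || any(idx0 > grid$dims - 1L))
    stop("coordinate (", paste(coord, collapse = ", "),
         ") falls outside the grid")
  as.integer(idx0 + 1L)
}

#' @rdname mni_to_voxel
#' @param voxel 1-based voxel index triple.
#' @export
voxel_to_mni <- function(voxel, grid) {
  stopifnot(inherits(grid, "volume_grid"), length(voxel) == 3L)
  as.numeric((grid$affine %*% c(voxel - 1, 1))[1:3])
}

# nearest integer, .5 rounded away from zero (not banker's rounding)
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}
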