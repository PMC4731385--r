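#' 3D image volume
#'
#' A lightweight container for a 3D scalar image: the voxel grid, the voxel
#' dimensions in mm, and the 4x4 voxel-index-to-world affine. All pipeline
#' stages consume and produce `flair_volume` objects; files are read once at
#' the boundary via [read_volume()].
#'
#' Voxel indices are 0-based in the affine convention: world coordinates of
#' voxel `(i, j, k)` (0-based) are `affine %*% c(i, j, k, 1)`.
#'
#' @param data numeric 3D array.
#' @param voxel_dims length-3 positive numeric, voxel size in mm.
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal scaling by
#'   `voxel_dims` with the origin at voxel (0,0,0).
#' @return An object of class `flair_volume` with elements `data`,
#'   `voxel_dims`, `affine`.
#' @export
flair_volume <- function(data, voxel_dims = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("non-3D input: 'data' must be a 3D array")
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stop("voxel_dims must be three strictly positive finite values")
  if (is.null(affine)) {
    affine <- diag(c(voxel_dims, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_dims = voxel_dims, affine = affine),
            class = "flair_volume")
}

#' @export
print.flair_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<flair_volume> %d x %d x %d, voxel %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.flair_volume <- function(x) dim(x$data)

#' Binary mask on a volume grid
#'
#' @param data logical 3D array (numeric arrays are coerced with `!= 0`).
#' @param parent a [flair_volume()] supplying geometry, or `NULL` with
#'   explicit `voxel_dims`/`affine`.
#' @param voxel_dims,affine geometry, used when `parent` is `NULL`.
#' @return Object of class `flair_mask` with elements `data` (logical array),
#'   `voxel_dims`, `affine`.
#' @export
flair_mask <- function(data, parent = NULL, voxel_dims = c(1, 1, 1),
                       affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array")
  if (!is.logical(data)) data <- array(data != 0, dim(data))
  if (!is.null(parent)) {
    if (!all(dim(data) == dim(parent$data)))
      stop("mask shape does not match parent volume shape")
    voxel_dims <- parent$voxel_dims
    affine <- parent$affine
  } else if (is.null(affine)) {
    affine <- diag(c(voxel_dims, 1))
  }
  structure(list(data = data, voxel_dims = as.numeric(voxel_dims),
                 affine = as.matrix(affine)),
            class = "flair_mask")
}

#' @export
dim.flair_mask <- function(x) dim(x$data)

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 image (optionally gzipped) into a
#' [flair_volume()]. 4D images with a singleton trailing dimension are
#' squeezed; other non-3D images are rejected. NaNs in the data are an
#' error unless `nan` is `"zero"`, in which case they are replaced by 0
#' (intended for values outside the brain mask).
#'
#' @param path file path to a `.nii` or `.nii.gz` image.
#' @param nan one of `"error"` (default) or `"zero"`.
#' @return A [flair_volume()].
#' @export
read_volume <- function(path, nan = c("error", "zero")) {
  nan <- match.arg(nan)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 4L && d[4] == 1L) {
    a <- array(a, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("non-3D input: image has ", length(d), " dimensions")
  if (anyNA(a)) {
    if (nan == "zero") a[is.na(a)] <- 0 else
      stop("input volume contains NaN values")
  }
  vd <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  if (abs(det(aff)) < 1e-12) aff <- diag(c(vd, 1))
  flair_volume(array(as.double(a), d), voxel_dims = abs(vd), affine = aff)
}

#' Write a volume or mask to NIfTI
#'
#' Data round-trips within the storage precision of the chosen datatype and
#' geometry exactly. Probability/intensity volumes are stored as 32-bit
#' float, masks as unsigned 8-bit.
#'
#' @param v a [flair_volume()] or [flair_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype string passed to RNifti (default
#'   `"float"` for volumes, `"uint8"` for masks).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = NULL) {
  is_mask <- inherits(v, "flair_mask")
  if (!is_mask && !inherits(v, "flair_volume"))
    stop("v must be a flair_volume or flair_mask")
  if (is.null(datatype)) datatype <- if (is_mask) "uint8" else "float"
  a <- if (is_mask) array(as.integer(v$data), dim(v$data)) else v$data
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- v$voxel_dims
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path file path; any nonzero voxel becomes `TRUE`.
#' @return A [flair_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  flair_mask(v$data != 0, parent = v)
}

#' Voxel volume in cubic millimetres
#'
#' @param v a [flair_volume()] or [flair_mask()].
#' @return `dx * dy * dz` in mm^3.
#' @export
voxel_volume_mm3 <- function(v) prod(v$voxel_dims)

# world coordinates (mm) of 0-based voxel indices; idx is an n x 3 matrix
voxel_to_world <- function(affine, idx) {
  idx <- cbind(idx, 1)
  t(affine %*% t(idx))[, 1:3, drop = FALSE]
}

# n x 3 matrix of 0-based voxel indices for linear array indices
linear_to_ijk <- function(lin, shape) {
  lin0 <- lin - 1L
  i <- lin0 %% shape[1]
  j <- (lin0 %/% shape[1]) %% shape[2]
  k <- lin0 %/% (shape[1] * shape[2])
  cbind(i, j, k)
}

stopifnot_same_grid <- function(a, b) {
  if (!all(dim(a$data) == dim(b$data)))
    stop("shape mismatch between volumes/masks")
  invisible(TRUE)
}
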