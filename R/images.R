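#' Volumetric image
#'
#' A 3D scalar grid with a 4x4 voxel-to-world affine (NIfTI convention: the
#' affine maps zero-based voxel indices to world mm). CT volumes carry
#' Hounsfield units; feature images are dimensionless.
#'
#' @param voxels 3D numeric array.
#' @param affine 4x4 voxel-index-to-world matrix. Defaults to isotropic 1 mm.
#' @return An object of class `vol_image` with fields `voxels` and `affine`.
#' @export
vol_image <- function(voxels, affine = diag(4)) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array, got ", length(dim(voxels)), " dimensions")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  if (anyNA(voxels))
    stop("volume contains ", sum(is.na(voxels)), " NaN/NA voxels")
  sp <- vox_spacing(affine)
  if (any(sp <= 0)) stop("voxel spacing must be positive")
  structure(list(voxels = voxels, affine = affine),
            class = "vol_image")
}

#' Binary mask on an image grid
#'
#' @param voxels 3D array with values strictly in \{0, 1\}.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `binary_mask` (also a `vol_image`).
#' @export
binary_mask <- function(voxels, affine = diag(4)) {
  u <- unique(as.vector(voxels))
  if (!all(u %in% c(0, 1)))
    stop("mask values must be 0 or 1; found: ",
         paste(utils::head(setdiff(u, c(0, 1)), 3), collapse = ", "))
  out <- vol_image(voxels, affine)
  class(out) <- c("binary_mask", "vol_image")
  out
}

#' Voxel spacing from an affine
#'
#' Column norms of the direction block, i.e. the physical step (mm) per voxel
#' along each image axis.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Numeric length-3 spacing in mm.
#' @export
vox_spacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

grid_dim <- function(img) dim(img$voxels)

#' @export
print.vol_image <- function(x, ...) {
  d <- dim(x$voxels)
  sp <- vox_spacing(x$affine)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Check that two images share a grid
#'
#' Shapes must match exactly and affines agree entrywise within `tol` mm.
#' @param a,b `vol_image` objects.
#' @param tol absolute tolerance on affine entries (mm).
#' @return TRUE/FALSE.
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$affine - b$affine) < tol)
}

stopifnot_same_grid <- function(a, b, what = "images") {
  if (!same_grid(a, b)) stop(what, " are not on the same grid")
  invisible(TRUE)
}

is_axis_aligned <- function(affine, tol = 1e-6) {
  R <- affine[1:3, 1:3]
  all(abs(R[row(R) != col(R)]) < tol) && all(diag(R) > 0)
}

# world mm -> zero-based continuous voxel index
world_to_voxel <- function(pts, affine) {
  pts <- as.matrix(pts)
  h <- cbind(pts, 1)
  t(solve(affine) %*% t(h))[, 1:3, drop = FALSE]
}

# zero-based voxel index -> world mm
voxel_to_world <- function(idx, affine) {
  idx <- as.matrix(idx)
  h <- cbind(idx, 1)
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

#' Landmark set
#'
#' Ordered, uniquely identified 3D points in world mm. Paired sets (source
#' and target of a registration) must share the same id sequence.
#'
#' @param id character vector of unique identifiers.
#' @param x,y,z numeric world coordinates (mm).
#' @return A `landmark_set` (a data frame with columns id, x, y, z).
#' @export
landmark_set <- function(id, x, y, z) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("landmark ids must be unique")
  xyz <- cbind(x, y, z)
  if (!all(is.finite(xyz))) stop("landmark coordinates must be finite")
  structure(data.frame(id = id, x = as.numeric(x), y = as.numeric(y),
                       z = as.numeric(z), stringsAsFactors = FALSE),
            class = c("landmark_set", "data.frame"))
}

lmk_matrix <- function(lmk) as.matrix(lmk[, c("x", "y", "z")])

check_paired <- function(a, b) {
  if (!identical(a$id, b$id))
    stop("landmark sets are not paired: id sequences differ")
  invisible(TRUE)
}
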