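#' Apply a voxel-to-world affine to 0-based voxel indices
#'
#' @param voxels numeric matrix (n x 3) of 0-based voxel indices, or a length-3
#'   vector.
#' @param affine 4 x 4 voxel-to-world matrix (mm, voxel-centre convention).
#' @return n x 3 matrix of world coordinates in mm.
#' @seealso [world_to_voxel()]
#' @export
voxel_to_world <- function(voxels, affine) {
  voxels <- to_point_matrix(voxels)
  check_affine(affine)
  h <- cbind(voxels, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

#' Map world coordinates to 0-based voxel indices
#'
#' Applies the inverse affine and rounds each coordinate to the nearest
#' integer, with ties rounded half away from zero (voxel-centre convention).
#'
#' @param points numeric matrix (n x 3) of world coordinates in mm, or a
#'   length-3 vector.
#' @param affine 4 x 4 voxel-to-world matrix; must be invertible.
#' @return integer n x 3 matrix of 0-based voxel indices.
#' @export
world_to_voxel <- function(points, affine) {
  points <- to_point_matrix(points)
  check_affine(affine)
  inv <- solve(affine)
  h <- cbind(points, 1) %*% t(inv)
  v <- h[, 1:3, drop = FALSE]
  round_half_away(v)
}

# round to nearest integer, ties away from zero (R's round() is banker's)
round_half_away <- function(x) {
  out <- sign(x) * floor(abs(x) + 0.5)
  storage.mode(out) <- "integer"
  out
}

to_point_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stopf("a point must have 3 coordinates")
    x <- matrix(x, ncol = 3L)
  }
  if (ncol(x) != 3L) stopf("points must be an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      !all(is.finite(affine))) {
    stopf("affine must be a finite 4 x 4 matrix")
  }
  if (abs(det(affine)) < .Machine$double.eps * 64) {
    stopf("affine is singular")
  }
  invisible(affine)
}
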