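#' Voxel grid with world geometry
#'
#' A `bb_grid` couples an array shape with a 4x4 voxel-to-world affine in
#' the RAS+ millimetre convention (+x left-to-right, +y posterior-to-anterior,
#' +z inferior-to-superior). Voxel indices are 0-based continuous coordinates,
#' matching the NIfTI convention, so the world position of voxel `(i,j,k)` is
#' `affine %*% c(i,j,k,1)`.
#'
#' @param shape integer vector of length 3, voxels per axis (all positive).
#' @param affine numeric 4x4 matrix mapping 0-based voxel indices to world mm;
#'   must be invertible with last row `(0,0,0,1)`.
#' @return an object of class `bb_grid` with elements `shape` and `affine`.
#' @export
bb_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("'shape' must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of 'affine' must be (0, 0, 0, 1)")
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps * 100)
    stop("'affine' is not invertible")
  if (any(grid_spacing_raw(affine) <= 0))
    stop("voxel sizes must be strictly positive")
  structure(list(shape = shape, affine = affine), class = "bb_grid")
}

grid_spacing_raw <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' @export
format.bb_grid <- function(x, ...) {
  sp <- signif(grid_spacing(x), 4)
  sprintf("<bb_grid %s voxels, %s mm>", paste(x$shape, collapse = "x"),
          paste(sp, collapse = "x"))
}

#' @export
print.bb_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Voxel spacing of a grid
#'
#' Column norms of the 3x3 block of the affine: physical size of one voxel
#' step along each array axis, in mm.
#'
#' @param g a [bb_grid].
#' @return numeric length-3 vector of voxel sizes (mm).
#' @export
grid_spacing <- function(g) grid_spacing_raw(g$affine)

#' Convert between world (mm) and voxel coordinates
#'
#' `world_to_voxel()` maps world RAS+ mm points to continuous 0-based voxel
#' indices; `voxel_to_world()` is its exact inverse. Points outside the grid
#' simply return out-of-range indices; no clipping is applied.
#'
#' @param g a [bb_grid].
#' @param points numeric N x 3 matrix (or length-3 vector) of coordinates.
#' @return N x 3 matrix of converted coordinates.
#' @export
world_to_voxel <- function(g, points) {
  pts <- as_points(points)
  inv <- solve(g$affine)
  out <- cbind(pts, 1) %*% t(inv[1:3, , drop = FALSE])
  dimnames(out) <- NULL
  out
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(g, points) {
  pts <- as_points(points)
  out <- cbind(pts, 1) %*% t(g$affine[1:3, , drop = FALSE])
  dimnames(out) <- NULL
  out
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) %% 3L != 0L) stop("points must be N x 3")
    points <- matrix(points, ncol = 3, byrow = TRUE)
  }
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("points must be N x 3")
  storage.mode(pts) <- "double"
  pts
}

# 0-based voxel index triples for every voxel of the grid (or a sub-box),
# ordered to match R's column-major array layout.
grid_voxel_indices <- function(g, lo = c(0L, 0L, 0L), hi = g$shape - 1L) {
  i <- lo[1]:hi[1]; j <- lo[2]:hi[2]; k <- lo[3]:hi[3]
  ni <- length(i); nj <- length(j); nk <- length(k)
  cbind(rep.int(i, nj * nk),
        rep.int(rep(j, each = ni), nk),
        rep(k, each = ni * nj))
}

# World coordinates of voxel centers of the grid (or a sub-box).
grid_world_coords <- function(g, lo = c(0L, 0L, 0L), hi = g$shape - 1L) {
  voxel_to_world(g, grid_voxel_indices(g, lo, hi))
}

# Grid of a sub-box [lo, hi] (0-based inclusive voxel bounds) sharing the
# parent's world frame.
subgrid <- function(g, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  aff <- g$affine
  aff[1:3, 4] <- voxel_to_world(g, lo)
  bb_grid(hi - lo + 1L, aff)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}
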