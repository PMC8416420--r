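#' Rigid-body transform
#'
#' Six-parameter rotation + translation in world mm. Rotation is specified
#' by Euler angles about the fixed world axes applied in the order x, then
#' y, then z; the forward map of a point p is
#' `R %*% (p - center) + center + translation`.
#'
#' @param rotation length-3 Euler angles in radians (x, y, z order).
#' @param translation length-3 translation in mm.
#' @param center rotation center in world mm.
#' @return an object of class `bb_rigid`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L)
  t <- structure(list(rotation = as.numeric(rotation),
                      translation = as.numeric(translation),
                      center = as.numeric(center)), class = "bb_rigid")
  R <- rotation_matrix(t$rotation)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("rotation matrix is not a proper rotation")
  t
}

rotation_matrix <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' @export
print.bb_rigid <- function(x, ...) {
  cat(sprintf("<bb_rigid> rot (deg): %s; trans (mm): %s\n",
              paste(signif(x$rotation * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

#' 4x4 homogeneous matrix of a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return 4x4 matrix acting on world RAS+ mm column vectors.
#' @export
rigid_matrix <- function(t) {
  R <- rotation_matrix(t$rotation)
  offset <- t$center + t$translation - R %*% t$center
  rbind(cbind(R, offset), c(0, 0, 0, 1))
}

#' Compose and invert affine maps
#'
#' `compose_affines(a, b)` returns the map "apply b, then a" as a 4x4
#' matrix; `invert_affine()` the inverse map. Both accept [rigid_transform()]
#' objects or plain 4x4 matrices.
#'
#' @param a,b,t transforms (`bb_rigid` or 4x4 matrix).
#' @return a 4x4 matrix.
#' @export
compose_affines <- function(a, b) as_affine(a) %*% as_affine(b)

#' @rdname compose_affines
#' @export
invert_affine <- function(t) solve(as_affine(t))

as_affine <- function(t) {
  if (inherits(t, "bb_rigid")) return(rigid_matrix(t))
  m <- as.matrix(t)
  if (!identical(dim(m), c(4L, 4L))) stop("expected a bb_rigid or 4x4 matrix")
  m
}

apply_affine_points <- function(m, points) {
  pts <- as_points(points)
  out <- cbind(pts, 1) %*% t(m[1:3, , drop = FALSE])
  dimnames(out) <- NULL
  out
}

#' Read and write affine transforms as plain text
#'
#' Four whitespace-separated rows of four numbers (world mm, RAS+).
#'
#' @param t transform (`bb_rigid` or 4x4 matrix).
#' @param path file path.
#' @return `read_affine_text()` returns a 4x4 matrix.
#' @export
write_affine_text <- function(t, path) {
  m <- as_affine(t)
  utils::write.table(format(m, digits = 17), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_affine_text
#' @export
read_affine_text <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(4L, 4L))) stop("expected 4 rows of 4 numbers")
  m
}

#' Dense displacement field
#'
#' Per-voxel world-mm displacement vectors on a grid. Fields are applied in
#' the pull convention: a point x in the target space maps to
#' `x + d(x)` in the source space, with `d` sampled by trilinear
#' interpolation (zero outside the field's grid).
#'
#' @param vectors numeric array of shape `grid$shape x 3`.
#' @param grid a [bb_grid].
#' @return an object of class `bb_dispfield`.
#' @export
displacement_field <- function(vectors, grid) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || !identical(as.integer(d[1:3]), grid$shape) || d[4] != 3L)
    stop("vectors must have shape grid$shape x 3")
  if (any(!is.finite(vectors))) stop("displacement field must be finite")
  structure(list(vectors = vectors, grid = grid), class = "bb_dispfield")
}

# Sample a displacement field at world points (N x 3) -> N x 3 mm vectors.
dispfield_at <- function(f, points) {
  vox <- world_to_voxel(f$grid, points)
  cbind(interp_at_voxel(f$vectors[, , , 1], vox),
        interp_at_voxel(f$vectors[, , , 2], vox),
        interp_at_voxel(f$vectors[, , , 3], vox))
}

#' Read and write displacement fields as 3-vector NIfTI volumes
#'
#' Stored with `dim[4] = 1`, `dim[5] = 3` and the vector intent code, the
#' usual convention for nonlinear warp fields.
#'
#' @param f a [displacement_field()].
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `read_dispfield()` returns a [displacement_field()].
#' @export
write_dispfield <- function(f, path) {
  d <- f$grid$shape
  arr <- array(f$vectors, dim = c(d, 1L, 3L))
  img <- RNifti::asNifti(arr)
  img$intent_code <- 1007L  # NIFTI_INTENT_VECTOR
  RNifti::sform(img) <- structure(f$grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_dispfield
#' @export
read_dispfield <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 5L) {
    if (d[4] != 1L || d[5] != 3L) stop("expected a dim[5]=3 vector volume")
    vec <- array(as.numeric(img), dim = d)[, , , 1, , drop = FALSE]
    vec <- array(vec, dim = c(d[1:3], 3L))
  } else if (length(d) == 4L && d[4] == 3L) {
    vec <- array(as.numeric(img), dim = d)
  } else stop("expected a displacement-field NIfTI (…x3 vectors)")
  g <- bb_grid(d[1:3], unclass(RNifti::xform(img, useQuaternionFirst = FALSE)))
  displacement_field(vec, g)
}

# ---- mask warping ---------------------------------------------------------

# Pull a binary mask onto target_grid: for each candidate target voxel
# center y, interpolate the source 0/1 field at pull_fn(y) (world -> world)
# and threshold at 0.5. Work is restricted to a candidate world box that is
# grown until no mask voxel touches its faces (or it covers the grid).
pull_mask_values <- function(m, pull_fn, points) {
  src <- pull_fn(points)
  interp_at_voxel(m$data, world_to_voxel(m$grid, src), "trilinear")
}

pull_mask_on_grid <- function(m, target_grid, pull_fn, bbox_world,
                              max_grow = 10L) {
  sp <- grid_spacing(target_grid)
  grow <- 4 * max(sp)
  for (iter in seq_len(max_grow)) {
    box <- voxel_box(target_grid, bbox_world$lo, bbox_world$hi, pad = 2L)
    if (is.null(box)) stop("transformed mask is empty on the target grid")
    w <- grid_world_coords(target_grid, box$lo, box$hi)
    vals <- pull_mask_values(m, pull_fn, w) >= 0.5
    dims <- box$hi - box$lo + 1L
    sub <- array(as.numeric(vals), dim = dims)
    covers <- all(box$lo == 0L) && all(box$hi == target_grid$shape - 1L)
    if (covers || !mask_touches_boundary(sub, box, target_grid$shape)) {
      data <- array(0, dim = target_grid$shape)
      data[(box$lo[1] + 1):(box$hi[1] + 1),
           (box$lo[2] + 1):(box$hi[2] + 1),
           (box$lo[3] + 1):(box$hi[3] + 1)] <- sub
      if (sum(data) == 0) stop("transformed mask is empty on the target grid")
      return(data)
    }
    bbox_world$lo <- bbox_world$lo - grow
    bbox_world$hi <- bbox_world$hi + grow
  }
  stop("mask bounding box failed to stabilize")
}

# TRUE if any nonzero voxel lies on a face of the sub-box that is not
# already a face of the full grid.
mask_touches_boundary <- function(sub, box, shape) {
  d <- dim(sub)
  for (ax in 1:3) {
    if (box$lo[ax] > 0L) {
      face <- switch(ax, sub[1, , ], sub[, 1, ], sub[, , 1])
      if (any(face != 0)) return(TRUE)
    }
    if (box$hi[ax] < shape[ax] - 1L) {
      face <- switch(ax, sub[d[1], , ], sub[, d[2], ], sub[, , d[3]])
      if (any(face != 0)) return(TRUE)
    }
  }
  FALSE
}

# World-mm bounding box of the nonzero voxels of a mask.
mask_world_bbox <- function(m) {
  idx <- which(m$data != 0)
  if (length(idx) == 0) stop("mask is empty")
  vox <- arrayInd(idx, dim(m$data)) - 1
  corners <- as.matrix(expand.grid(range(vox[, 1]), range(vox[, 2]),
                                   range(vox[, 3])))
  w <- voxel_to_world(m$grid, corners)
  list(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' Apply a spatial transform to a block mask
#'
#' The mask's 0/1 field is trilinearly interpolated at the transformed
#' target voxel centers and re-binarized at 0.5 (less aliasing on thin slabs
#' than nearest-neighbor). Rigid/affine transforms are given in the
#' `"forward"` convention by default (the motion of the mask) and inverted
#' internally; displacement fields are pull-only (target point x samples the
#' source at `x + d(x)`). Compose transforms *before* applying: a single
#' resampling step is performed.
#'
#' @param m a [bb_mask].
#' @param transform a [rigid_transform()], 4x4 affine matrix, or
#'   [displacement_field()].
#' @param target a [bb_grid] for the output (defaults to the mask's grid).
#' @param convention `"forward"` (mask motion; rigid/affine only) or
#'   `"pull"` (transform maps target points to source points).
#' @param method method tag for the returned mask (defaults to the input's).
#' @return a [bb_mask] on `target`; `slab_index` is `NA` unless the caller
#'   re-establishes slab alignment.
#' @export
apply_transform_to_mask <- function(m, transform, target = m$grid,
                                    convention = c("forward", "pull"),
                                    method = m$method) {
  convention <- match.arg(convention)
  bb <- mask_world_bbox(m)
  if (inherits(transform, "bb_dispfield")) {
    if (convention == "forward")
      stop("displacement fields are applied in the pull convention")
    f <- transform
    pull_fn <- function(p) p + dispfield_at(f, p)
    amax <- sqrt(max(rowSums(matrix(f$vectors, ncol = 3)^2)))
    bbox <- list(lo = bb$lo - amax, hi = bb$hi + amax)
  } else {
    fwd <- as_affine(transform)
    pull <- if (convention == "forward") solve(fwd) else fwd
    pull_fn <- function(p) apply_affine_points(pull, p)
    inv_of_pull <- solve(pull)  # maps source points to target points
    corners <- as.matrix(expand.grid(c(bb$lo[1], bb$hi[1]),
                                     c(bb$lo[2], bb$hi[2]),
                                     c(bb$lo[3], bb$hi[3])))
    tc <- apply_affine_points(inv_of_pull, corners)
    bbox <- list(lo = apply(tc, 2, min), hi = apply(tc, 2, max))
  }
  data <- pull_mask_on_grid(m, target, pull_fn, bbox)
  bb_mask(data, target, roi_label = m$roi_label, method = method,
          slab_index = NA_integer_,
          provenance = c(m$provenance, list(transformed = TRUE)))
}

#' Percent overlap between two block masks
#'
#' Fraction of the reference mask covered by the sample, as a percentage:
#' `100 * |sample ∩ reference| / |reference|`. The reference denominator is
#' the accuracy metric used throughout; `"sample"`, `"union"` and `"dice"`
#' denominators are available as secondary metrics.
#'
#' @param sample,reference [bb_mask]s on the same grid.
#' @param denominator which denominator to use.
#' @return a percentage in `[0, 100]`.
#' @export
percent_overlap <- function(sample, reference,
                            denominator = c("reference", "sample", "union",
                                            "dice")) {
  denominator <- match.arg(denominator)
  if (!grids_equal(sample$grid, reference$grid))
    stop("masks must be on the same grid (resample first)")
  nref <- sum(reference$data)
  if (nref == 0) stop("empty reference mask")
  inter <- sum(sample$data * reference$data)
  nsam <- sum(sample$data)
  100 * switch(denominator,
               reference = inter / nref,
               sample = inter / nsam,
               union = inter / (nref + nsam - inter),
               dice = 2 * inter / (nref + nsam))
}

#' Exhaustive anterior-posterior slab-offset search (guided sample)
#'
#' Translates the sample block by whole slabs along the AP axis and returns
#' the offset maximizing percent overlap with the reference — the
#' "neuroimaging-guided" correction: re-choosing the slice to sample while
#' keeping the in-plane position fixed. All offsets keeping the block inside
#' the stack are enumerated; ties are broken toward the smallest |k|, then
#' the smaller (more posterior) k. Since k = 0 is always admissible the
#' result is never worse than the original placement.
#'
#' @param sample a slab-constructed [bb_mask] (has a `slab_index`).
#' @param reference a [bb_mask] on the same grid.
#' @param stack the [make_slice_stack()] the sample was placed on.
#' @return a list of class `bb_overlap_result` with `percent_overlap`,
#'   `slab_offset` (k), `transform` (the AP translation as [rigid_transform()])
#'   and `moved_mask` (method `"guided"`).
#' @export
ap_slab_search <- function(sample, reference, stack) {
  if (!grids_equal(sample$grid, reference$grid))
    stop("masks must be on the same grid")
  if (is.na(sample$slab_index)) stop("sample is not slab-constructed")
  t <- stack$thickness_mm
  ks <- (-sample$slab_index):(stack$n_slabs - 1L - sample$slab_index)
  ridx <- which(reference$data == 1)
  if (length(ridx) == 0) stop("empty reference mask")
  rw <- voxel_to_world(reference$grid, arrayInd(ridx, dim(reference$data)) - 1)
  counts <- vapply(ks, function(k) {
    src <- rw; src[, 2] <- src[, 2] - k * t
    sum(interp_at_voxel(sample$data, world_to_voxel(sample$grid, src),
                        "trilinear") >= 0.5)
  }, numeric(1))
  best <- counts == max(counts)
  kbest <- ks[best]
  kbest <- kbest[order(abs(kbest), kbest)][1]
  tr <- rigid_transform(translation = c(0, kbest * t, 0))
  moved <- apply_transform_to_mask(sample, tr, sample$grid, method = "guided")
  moved$slab_index <- sample$slab_index + as.integer(kbest)
  structure(list(percent_overlap = percent_overlap(moved, reference),
                 slab_offset = as.integer(kbest), transform = tr,
                 moved_mask = moved),
            class = "bb_overlap_result")
}

#' @export
print.bb_overlap_result <- function(x, ...) {
  cat(sprintf("<bb_overlap_result> %.2f%% overlap\n", x$percent_overlap))
  invisible(x)
}
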