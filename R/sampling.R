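#' Coronal slab stack
#'
#' Partitions the anterior-posterior (AP, world y) extent of a grid into
#' contiguous, non-overlapping slabs of fixed thickness, emulating serial
#' coronal slicing of a fixed brain. Slabs are half-open intervals
#' `[origin + i*t, origin + (i+1)*t)` indexed from 0, so every voxel center
#' belongs to exactly one slab and a point on a boundary falls in the later
#' (more anterior) slab. Slabs are defined in world coordinates: on grids
#' oblique to the world axes they remain true coronal slabs.
#'
#' @param g a [bb_grid].
#' @param thickness_mm slab thickness in mm (> 0); 4 mm matches a standard
#'   autopsy slicing protocol.
#' @param origin_policy `"anterior_edge"` aligns the anterior face of the
#'   last slab with the most anterior voxel center (slicing counted from the
#'   frontal pole); `"posterior_edge"` anchors the first slab at the most
#'   posterior voxel center; `"fixed"` uses `origin_mm`.
#' @param origin_mm world y of the posterior face of slab 0 (only with
#'   `origin_policy = "fixed"`; must not exceed the posterior grid extent).
#' @return an object of class `bb_slice_stack` with fields `grid`, `axis`
#'   (always 2, the world y axis), `origin_mm`, `thickness_mm`, `n_slabs`.
#' @export
make_slice_stack <- function(g, thickness_mm = 4,
                             origin_policy = c("anterior_edge",
                                               "posterior_edge", "fixed"),
                             origin_mm = NULL) {
  origin_policy <- match.arg(origin_policy)
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1L || thickness_mm <= 0)
    stop("'thickness_mm' must be a positive number")
  yr <- grid_ap_range(g)
  eps <- 1e-6
  if (origin_policy == "anterior_edge") {
    top <- yr[2] + eps
    n <- ceiling((top - yr[1]) / thickness_mm)
    origin <- top - n * thickness_mm
  } else if (origin_policy == "posterior_edge") {
    origin <- yr[1]
    n <- floor((yr[2] - yr[1]) / thickness_mm) + 1L
  } else {
    if (is.null(origin_mm)) stop("'origin_mm' required for fixed origin")
    origin <- origin_mm
    if (origin > yr[1] + eps)
      stop("fixed origin must lie at or below the posterior grid extent")
    n <- ceiling((yr[2] + eps - origin) / thickness_mm)
  }
  structure(list(grid = g, axis = 2L, origin_mm = origin,
                 thickness_mm = thickness_mm, n_slabs = as.integer(n)),
            class = "bb_slice_stack")
}

# AP (world y) range of voxel centers: evaluated at the 8 grid corners,
# exact for affine maps.
grid_ap_range <- function(g) {
  hi <- g$shape - 1L
  corners <- as.matrix(expand.grid(c(0, hi[1]), c(0, hi[2]), c(0, hi[3])))
  range(voxel_to_world(g, corners)[, 2])
}

#' @export
print.bb_slice_stack <- function(x, ...) {
  cat(sprintf("<bb_slice_stack> %d slabs of %g mm, AP origin %.2f mm\n",
              x$n_slabs, x$thickness_mm, x$origin_mm))
  invisible(x)
}

#' Slab containing a world point
#'
#' @param stack a [make_slice_stack()] result.
#' @param p world point (length-3 mm) or N x 3 matrix.
#' @return 0-based slab index (or vector of indices).
#' @export
slab_of_point <- function(stack, p) {
  pts <- as_points(p)
  idx <- floor((pts[, 2] - stack$origin_mm) / stack$thickness_mm)
  if (any(idx < 0 | idx >= stack$n_slabs))
    stop("point outside the slab stack extent")
  as.integer(idx)
}

# Half-open world AP interval [lo, hi) of a slab.
slab_interval <- function(stack, slab_index) {
  stack$origin_mm + c(slab_index, slab_index + 1) * stack$thickness_mm
}

#' Block mask
#'
#' A binary volume marking one sampled tissue block, tagged with its region
#' label, how it was placed, and (for slab-constructed blocks) which slab it
#' occupies.
#'
#' @param data binary 3D array (values 0/1, at least one voxel set).
#' @param grid the [bb_grid] the mask lives on.
#' @param roi_label region label, e.g. `"MFG"`.
#' @param method one of `"subject_specific"`, `"target"`, `"reference"`,
#'   `"guided"`, `"optimal"`.
#' @param slab_index 0-based slab index, or `NA` when the block is no longer
#'   slab-aligned (after rigid-body optimization).
#' @param provenance free-form list recording how the mask was made.
#' @return an object of class `c("bb_mask", "bb_volume")`.
#' @export
bb_mask <- function(data, grid, roi_label = "block",
                    method = c("subject_specific", "target", "reference",
                               "guided", "optimal"),
                    slab_index = NA_integer_, provenance = list()) {
  method <- match.arg(method)
  v <- bb_volume(data, grid)
  if (!all(v$data %in% c(0, 1))) stop("mask values must be 0/1")
  if (sum(v$data) == 0) stop("empty block")
  structure(list(data = v$data, grid = grid, roi_label = roi_label,
                 method = method, slab_index = slab_index,
                 provenance = provenance),
            class = c("bb_mask", "bb_volume"))
}

#' @export
print.bb_mask <- function(x, ...) {
  cat(sprintf("<bb_mask> %s [%s], %d voxels, slab %s\n", x$roi_label,
              x$method, sum(x$data),
              if (is.na(x$slab_index)) "-" else x$slab_index))
  invisible(x)
}

mask_voxel_count <- function(m) sum(m$data)

#' World centroid of a mask
#'
#' Mean world position of the nonzero voxel centers.
#'
#' @param m a [bb_mask].
#' @return length-3 world mm vector.
#' @export
mask_centroid <- function(m) {
  idx <- which(m$data == 1)
  vox <- arrayInd(idx, dim(m$data)) - 1
  colMeans(voxel_to_world(m$grid, vox))
}

#' Place a rectangular block on a slab
#'
#' The block is the axis-aligned world box spanned by an in-plane rectangle
#' (left-right width x inferior-superior height, centered at
#' `center_in_plane_mm`) and the AP interval of slab `slab_index`. A voxel
#' belongs to the block when its center lies inside the box; all intervals
#' are half-open, so abutting blocks never share voxels.
#'
#' @param stack a [make_slice_stack()] result.
#' @param slab_index 0-based slab index.
#' @param center_in_plane_mm length-2 world (x, z) center of the rectangle.
#' @param size_mm length-2 (width, height) in mm; the default 38 x 32 mm is
#'   the standard neuropathology block footprint.
#' @param roi_label,method,provenance passed to [bb_mask()].
#' @return a [bb_mask] on the stack's grid.
#' @export
place_block <- function(stack, slab_index, center_in_plane_mm,
                        size_mm = c(38, 32), roi_label = "block",
                        method = "target", provenance = list()) {
  if (slab_index < 0 || slab_index >= stack$n_slabs)
    stop("slab_index out of range")
  if (any(size_mm <= 0)) stop("block size must be strictly positive")
  g <- stack$grid
  yint <- slab_interval(stack, slab_index)
  lo <- c(center_in_plane_mm[1] - size_mm[1] / 2, yint[1],
          center_in_plane_mm[2] - size_mm[2] / 2)
  hi <- c(center_in_plane_mm[1] + size_mm[1] / 2, yint[2],
          center_in_plane_mm[2] + size_mm[2] / 2)
  box <- voxel_box(g, lo, hi)
  data <- array(0, dim = g$shape)
  if (!is.null(box)) {
    w <- grid_world_coords(g, box$lo, box$hi)
    inside <- w[, 1] >= lo[1] & w[, 1] < hi[1] &
              w[, 2] >= lo[2] & w[, 2] < hi[2] &
              w[, 3] >= lo[3] & w[, 3] < hi[3]
    sub <- array(as.numeric(inside), dim = box$hi - box$lo + 1L)
    data[(box$lo[1] + 1):(box$hi[1] + 1),
         (box$lo[2] + 1):(box$hi[2] + 1),
         (box$lo[3] + 1):(box$hi[3] + 1)] <- sub
  }
  if (sum(data) == 0) stop("empty block: box lies outside the grid")
  prov <- c(provenance,
            list(center_in_plane_mm = as.numeric(center_in_plane_mm),
                 size_mm = as.numeric(size_mm),
                 thickness_mm = stack$thickness_mm))
  bb_mask(data, g, roi_label = roi_label, method = method,
          slab_index = as.integer(slab_index), provenance = prov)
}

# 0-based voxel index bounds of the voxels whose centers can lie in the
# world box [lo, hi); NULL when the box misses the grid entirely.
voxel_box <- function(g, lo, hi, pad = 1L) {
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  vox <- world_to_voxel(g, corners)
  vlo <- pmax(floor(apply(vox, 2, min)) - pad, 0)
  vhi <- pmin(ceiling(apply(vox, 2, max)) + pad, g$shape - 1L)
  if (any(vlo > vhi)) return(NULL)
  list(lo = as.integer(vlo), hi = as.integer(vhi))
}

#' Place a block anchored to an anatomical landmark
#'
#' Emulates the traditional neuropathologic rule "sample region R on the
#' slice containing landmark L, at a known position relative to L": the
#' block occupies the slab containing the landmark (plus a protocol slab
#' offset for regions sampled on other slices) and is centered at the
#' landmark's in-plane position plus `roi_offset_mm`.
#'
#' @param stack a [make_slice_stack()] result.
#' @param landmark_mm world position (length 3) of the landmark, e.g. an
#'   anterior-commissure analogue.
#' @param roi_offset_mm length-2 in-plane (x, z) offset from the landmark to
#'   the block center.
#' @param size_mm block footprint, see [place_block()].
#' @param slab_offset integer number of slabs between the landmark slice and
#'   the target slice (0 = same slice).
#' @param roi_label,method,provenance passed to [bb_mask()].
#' @return a [bb_mask] with `method = "subject_specific"` by default.
#' @export
landmark_anchored_block <- function(stack, landmark_mm, roi_offset_mm,
                                    size_mm = c(38, 32), slab_offset = 0L,
                                    roi_label = "block",
                                    method = "subject_specific",
                                    provenance = list()) {
  slab <- slab_of_point(stack, landmark_mm) + as.integer(slab_offset)
  slab <- max(0L, min(stack$n_slabs - 1L, slab))
  center <- c(landmark_mm[1] + roi_offset_mm[1],
              landmark_mm[3] + roi_offset_mm[2])
  place_block(stack, slab, center, size_mm = size_mm, roi_label = roi_label,
              method = method,
              provenance = c(provenance,
                             list(landmark_mm = as.numeric(landmark_mm),
                                  roi_offset_mm = as.numeric(roi_offset_mm),
                                  slab_offset = as.integer(slab_offset))))
}

#' Read and write block specification tables
#'
#' Tab-separated tables with columns `roi_label`, `slab_index`,
#' `center_x_mm`, `center_z_mm`, `width_mm`, `height_mm`.
#'
#' @param specs a data.frame with the columns above.
#' @param path file path.
#' @return `read_block_specs()` returns the data.frame.
#' @export
write_block_specs <- function(specs, path) {
  need <- c("roi_label", "slab_index", "center_x_mm", "center_z_mm",
            "width_mm", "height_mm")
  if (!all(need %in% names(specs))) stop("missing block spec columns")
  utils::write.table(specs[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_block_specs
#' @export
read_block_specs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
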