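#' Spherical region set
#'
#' Builds voxel masks for a set of regions given their center coordinates —
#' the conventional sphere parcellation used with functionally defined
#' region sets. A voxel belongs to a region when its center lies within
#' `radius_mm` of the region center; regions may overlap. Regions with no
#' voxels on the grid are flagged empty (and excluded from profiles).
#'
#' @param centers N x 3 matrix of region centers (world mm).
#' @param radius_mm sphere radius (> 0), default 5 mm.
#' @param grid the [bb_grid] to rasterize on.
#' @param ids optional region identifiers (default 1..N).
#' @return object of class `bb_region_set`: `ids`, `centers`, `radius_mm`,
#'   `grid`, `voxels` (list of linear voxel indices), `empty` (logical).
#' @export
make_sphere_regions <- function(centers, radius_mm = 5, grid, ids = NULL) {
  centers <- as_points(centers)
  if (radius_mm <= 0) stop("radius_mm must be positive")
  n <- nrow(centers)
  ids <- ids %||% seq_len(n)
  voxels <- vector("list", n)
  for (i in seq_len(n)) {
    box <- voxel_box(grid, centers[i, ] - radius_mm, centers[i, ] + radius_mm)
    if (is.null(box)) { voxels[[i]] <- integer(0); next }
    vox <- grid_voxel_indices(grid, box$lo, box$hi)
    w <- voxel_to_world(grid, vox)
    keep <- rowSums((w - rep(centers[i, ], each = nrow(w)))^2) <= radius_mm^2
    v <- vox[keep, , drop = FALSE]
    voxels[[i]] <- as.integer(1 + v[, 1] + grid$shape[1] *
                              (v[, 2] + grid$shape[2] * v[, 3]))
  }
  empty <- lengths(voxels) == 0L
  if (all(empty)) stop("all regions are empty on this grid")
  structure(list(ids = ids, centers = centers, radius_mm = radius_mm,
                 grid = grid, voxels = voxels, empty = empty),
            class = "bb_region_set")
}

#' @export
print.bb_region_set <- function(x, ...) {
  cat(sprintf("<bb_region_set> %d regions, radius %g mm (%d empty)\n",
              length(x$ids), x$radius_mm, sum(x$empty)))
  invisible(x)
}

#' Read and write region-center tables
#'
#' TSV with columns `id`, `x_mm`, `y_mm`, `z_mm` and optionally `radius_mm`.
#'
#' @param path file path.
#' @param rs a [make_sphere_regions()] result.
#' @return `read_region_table()` returns a data.frame.
#' @export
read_region_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_region_table
#' @export
write_region_table <- function(rs, path) {
  utils::write.table(
    data.frame(id = rs$ids, x_mm = rs$centers[, 1], y_mm = rs$centers[, 2],
               z_mm = rs$centers[, 3], radius_mm = rs$radius_mm),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean timeseries within a mask
#'
#' Per-timepoint arithmetic mean of the 4D series over the mask voxels. A
#' mask defined on a different (e.g. structural) grid is first resampled to
#' the functional grid (trilinear, 0.5 threshold).
#'
#' @param ts a [bb_volume4d].
#' @param mask a [bb_mask] (any grid in the same world frame).
#' @return numeric vector of length T.
#' @export
mean_timeseries <- function(ts, mask) {
  if (!grids_equal(mask$grid, ts$grid)) {
    rs <- resample_to_grid(bb_volume(mask$data, mask$grid), ts$grid,
                           "trilinear")
    vox <- which(rs$data >= 0.5)
  } else {
    vox <- which(mask$data == 1)
  }
  if (length(vox) == 0) stop("mask is empty on the functional grid")
  d <- dim(ts$data)
  mat <- matrix(ts$data, nrow = prod(d[1:3]))
  colMeans(mat[vox, , drop = FALSE])
}

# T x N matrix of mean series for every region in a region set (empty
# regions give NA columns).
region_timeseries <- function(ts, regions) {
  if (!grids_equal(regions$grid, ts$grid))
    stop("region set must be rasterized on the functional grid")
  d <- dim(ts$data)
  mat <- matrix(ts$data, nrow = prod(d[1:3]))
  out <- matrix(NA_real_, d[4], length(regions$ids))
  for (i in seq_along(regions$ids)) {
    v <- regions$voxels[[i]]
    if (length(v) > 0) out[, i] <- colMeans(mat[v, , drop = FALSE])
  }
  out
}

#' Seed-based functional connectivity profile
#'
#' Pearson correlation of a seed timeseries with each region's mean
#' timeseries. Zero-variance (or missing) region series give `NA` with the
#' `undefined` flag set rather than a silent 0.
#'
#' @param seed_series numeric vector (length T >= 3), non-constant.
#' @param region_series T x N matrix of region mean series.
#' @return list of class `bb_fc_profile`: `r` (length N), `undefined`
#'   (logical length N).
#' @export
fc_profile <- function(seed_series, region_series) {
  region_series <- as.matrix(region_series)
  T_ <- length(seed_series)
  if (T_ < 3) stop("need at least 3 timepoints")
  if (nrow(region_series) != T_) stop("series lengths differ")
  if (stats::sd(seed_series) == 0) stop("constant seed series")
  sds <- apply(region_series, 2, stats::sd)
  undefined <- !is.finite(sds) | sds == 0
  r <- rep(NA_real_, ncol(region_series))
  if (any(!undefined))
    r[!undefined] <- as.vector(stats::cor(seed_series,
                                          region_series[, !undefined,
                                                        drop = FALSE]))
  structure(list(r = r, undefined = undefined), class = "bb_fc_profile")
}

#' Compare connectivity of subject-specific vs reference samples
#'
#' Given per-subject FC profiles of the same seed region extracted from the
#' subject-specific block and from the reference block, computes per-region
#' differences `delta = r_subject_specific - r_reference`, and flags regions
#' with significantly increased or decreased connectivity with the
#' subject-specific sample via the sign-flip permutation test
#' ([sign_flip_null()]). Regions undefined (zero-variance) in any profile
#' are excluded as degenerate.
#'
#' @param r_subject_specific,r_reference n x R matrices of Pearson r (rows =
#'   subjects); `NA` marks undefined entries.
#' @param n_perm,alpha,seed,statistic passed to [sign_flip_null()].
#' @param fisher_z compare on the Fisher-z scale instead of raw r.
#' @return list of class `bb_fc_discrepancy`: `deltas` (n x R), `table`
#'   (per-region TSV-ready data.frame with mean delta, observed statistic,
#'   thresholds, flags), `increased`, `decreased` (region indices), `counts`.
#' @export
fc_discrepancy_analysis <- function(r_subject_specific, r_reference,
                                    n_perm = 1000L, alpha = 0.05, seed = 1L,
                                    statistic = "signed_count",
                                    fisher_z = FALSE) {
  a <- as.matrix(r_subject_specific); b <- as.matrix(r_reference)
  if (!all(dim(a) == dim(b))) stop("profile matrices differ in shape")
  if (nrow(a) < 3) stop("need at least 3 subjects")
  if (fisher_z) { a <- atanh(pmin(pmax(a, -1 + 1e-12), 1 - 1e-12))
                  b <- atanh(pmin(pmax(b, -1 + 1e-12), 1 - 1e-12)) }
  bad <- !is.finite(a) | !is.finite(b)
  deltas <- a - b
  deltas[bad] <- 0  # undefined pairs carry no evidence
  res <- sign_flip_null(deltas, n_perm = n_perm, alpha = alpha, seed = seed,
                        statistic = statistic)
  excluded <- colSums(bad) > 0 & colSums(!bad) == 0
  res$significant_up[excluded] <- FALSE
  res$significant_down[excluded] <- FALSE
  tab <- cbind(res, mean_delta = colMeans(deltas))
  structure(list(deltas = deltas, table = tab,
                 increased = which(res$significant_up),
                 decreased = which(res$significant_down),
                 counts = c(increased = sum(res$significant_up),
                            decreased = sum(res$significant_down))),
            class = "bb_fc_discrepancy")
}

#' @export
print.bb_fc_discrepancy <- function(x, ...) {
  cat(sprintf("<bb_fc_discrepancy> %d increased, %d decreased of %d regions\n",
              x$counts["increased"], x$counts["decreased"], ncol(x$deltas)))
  invisible(x)
}
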