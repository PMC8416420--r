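#' 3D and 4D volumes
#'
#' A `bb_volume` is a 3D scalar array bound to a [bb_grid]; a `bb_volume4d`
#' additionally carries a time axis with a repetition time in seconds. Data
#' must be finite everywhere (NaN handling at load time is controlled by the
#' reader).
#'
#' @param data numeric array; 3D for `bb_volume`, 4D (x, y, z, t) for
#'   `bb_volume4d`.
#' @param grid a [bb_grid] whose shape matches the spatial dimensions.
#' @param tr repetition time in seconds (4D only, > 0).
#' @return an object of class `bb_volume` or `bb_volume4d`.
#' @export
bb_volume <- function(data, grid) {
  if (!inherits(grid, "bb_grid")) stop("'grid' must be a bb_grid")
  data <- as.array(data)
  if (length(dim(data)) != 3L || !identical(as.integer(dim(data)), grid$shape))
    stop("data shape must equal grid shape")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume data contains non-finite values")
  structure(list(data = data, grid = grid), class = "bb_volume")
}

#' @rdname bb_volume
#' @export
bb_volume4d <- function(data, grid, tr) {
  if (!inherits(grid, "bb_grid")) stop("'grid' must be a bb_grid")
  data <- as.array(data)
  d <- dim(data)
  if (length(d) != 4L || !identical(as.integer(d[1:3]), grid$shape))
    stop("data must be 4D with spatial shape equal to grid shape")
  if (d[4] < 2L) stop("a timeseries needs at least 2 volumes")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("'tr' must be > 0")
  structure(list(data = data, grid = grid, tr = as.numeric(tr)),
            class = "bb_volume4d")
}

#' @export
print.bb_volume <- function(x, ...) {
  cat("<bb_volume>", format(x$grid), "\n")
  invisible(x)
}

#' @export
print.bb_volume4d <- function(x, ...) {
  cat(sprintf("<bb_volume4d> %s, T=%d, TR=%g s\n", format(x$grid),
              dim(x$data)[4], x$tr))
  invisible(x)
}

grid_from_nifti <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$sform_code == 0L && hdr$qform_code == 0L)
    stop("NIfTI file defines neither sform nor qform; cannot place it in space")
  bb_grid(dim(img)[1:3], unclass(aff))
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers around RNifti. The sform is preferred over the qform when
#' both are present; a file carrying neither is rejected. Data are returned
#' in native scale (the on-disk slope/intercept is applied). Non-finite
#' voxels are rejected by default or zero-filled with `nan = "zero"`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param nan `"error"` to reject non-finite voxels, `"zero"` to replace them
#'   with 0.
#' @return `read_volume()` returns a [bb_volume]; `read_volume4d()` a
#'   [bb_volume4d] with `tr` taken from `pixdim[4]` (seconds).
#' @export
read_volume <- function(path, nan = c("error", "zero")) {
  nan <- match.arg(nan)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
    g <- grid_from_nifti(img)
    return(bb_volume(clean_nan(img2, nan), g))
  }
  if (length(d) != 3L)
    stop("expected 3D volume, file has ", length(d), " dimensions")
  bb_volume(clean_nan(array(as.numeric(img), dim = d), nan), grid_from_nifti(img))
}

#' @rdname read_volume
#' @export
read_volume4d <- function(path, nan = c("error", "zero")) {
  nan <- match.arg(nan)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected 4D timeseries, file has ", length(d), " dimensions")
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) stop("file does not record a positive TR")
  bb_volume4d(clean_nan(array(as.numeric(img), dim = d), nan), grid_from_nifti(img), tr)
}

clean_nan <- function(a, nan) {
  bad <- !is.finite(a)
  if (any(bad)) {
    if (nan == "error") stop("volume data contains non-finite values")
    a[bad] <- 0
  }
  a
}

#' @param v a [bb_volume] or [bb_volume4d].
#' @param datatype on-disk datatype passed to [RNifti::writeNifti()]
#'   (`"auto"` picks a lossless type for integer-valued data).
#' @rdname read_volume
#' @export
write_volume <- function(v, path, datatype = "auto") {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(v$data)
  if (inherits(v, "bb_volume4d")) {
    pd <- c(grid_spacing(v$grid), v$tr)
    RNifti::pixdim(img) <- pd
  }
  RNifti::sform(img) <- structure(v$grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Resample a volume onto another grid
#'
#' Pull-style resampling: each target voxel center is mapped through both
#' affines into the source voxel frame and interpolated there. Both grids
#' must describe the same world frame. Target voxels falling outside the
#' source grid get the fill value 0.
#'
#' @param v a [bb_volume].
#' @param target a [bb_grid] to resample onto.
#' @param method `"trilinear"` or `"nearest"`.
#' @return a [bb_volume] on `target`.
#' @export
resample_to_grid <- function(v, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  vox <- world_to_voxel(v$grid, grid_world_coords(target))
  vals <- interp_at_voxel(v$data, vox, method)
  bb_volume(array(vals, dim = target$shape), target)
}

# Interpolate a 3D array at continuous 0-based voxel coordinates.
# Outside voxels contribute 0 (zero-padded field).
interp_at_voxel <- function(data, vox, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(data)
  if (method == "nearest") {
    idx <- round(vox)
    ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
          idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
          idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    out <- numeric(nrow(vox))
    if (any(ok)) {
      lin <- 1 + idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3])
      out[ok] <- data[lin]
    }
    return(out)
  }
  i0 <- floor(vox)
  f <- vox - i0
  out <- numeric(nrow(vox))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- i0[, 1] + di; jj <- i0[, 2] + dj; kk <- i0[, 3] + dk
    w <- (if (di) f[, 1] else 1 - f[, 1]) *
         (if (dj) f[, 2] else 1 - f[, 2]) *
         (if (dk) f[, 3] else 1 - f[, 3])
    ok <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1 &
          kk >= 0 & kk <= d[3] - 1 & w > 0
    if (any(ok)) {
      lin <- 1 + ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok])
      out[ok] <- out[ok] + w[ok] * data[lin]
    }
  }
  out
}
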