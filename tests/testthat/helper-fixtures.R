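# Shared in-code fixtures. Everything is generated at test time; the only
# file I/O goes through tempfiles.

# Small axis-aligned grid with optional voxel size and origin.
test_grid <- function(shape = c(20, 20, 20), voxel = 1,
                      origin = -(shape - 1) * voxel / 2) {
  a <- diag(c(rep(voxel, 3), 1))
  a[1:3, 4] <- origin
  bb_grid(shape, a)
}

# Grid rotated by `deg` about the world z axis (oblique to the AP axis).
rotated_grid <- function(shape = c(40, 40, 40), voxel = 1, deg = 20) {
  R <- brainblocks:::rotation_matrix(c(0, 0, deg * pi / 180))
  a <- rbind(cbind(R * voxel, -R %*% ((shape - 1) * voxel / 2)), c(0, 0, 0, 1))
  bb_grid(shape, a)
}

# Random blob mask: a filled ball at a random interior center.
random_ball_mask <- function(g, radius, label = "blob", method = "target") {
  ctr <- voxel_to_world(g, (g$shape - 1) / 2 +
                          stats::runif(3, -g$shape / 6, g$shape / 6))
  w <- brainblocks:::grid_world_coords(g)
  data <- array(as.numeric(rowSums(sweep(w, 2, as.vector(ctr))^2) <= radius^2),
                dim = g$shape)
  bb_mask(data, g, roi_label = label, method = method)
}

# Hand-written minimal uncompressed NIfTI-1 file (int16), independent of any
# NIfTI library: used as the oracle for on-disk slope/intercept handling.
write_nifti_raw <- function(path, data_int16, dims, slope, inter,
                            srows = diag(4)[1:3, ]) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 4) writeBin(as.integer(x), con, size = size,
                                       endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348)
  wc(36)
  wi(c(length(dims), dims, rep(1, 7 - length(dims))), size = 2)
  wf(c(0, 0, 0)); wi(0, size = 2)
  wi(4, size = 2); wi(16, size = 2); wi(0, size = 2)
  wf(c(1, rep(1, length(dims)), rep(0, 7 - length(dims))))
  wf(352); wf(slope); wf(inter)
  wi(0, size = 2); wc(1); wc(1)
  wf(c(0, 0, 0)); wf(0); wi(c(0, 0))
  wc(80); wc(24)
  wi(0, size = 2); wi(2, size = 2)
  wf(rep(0, 6))
  wf(srows[1, ]); wf(srows[2, ]); wf(srows[3, ])
  wc(16)
  writeChar("n+1", con, nchars = 3, eos = NULL); wc(1)
  wi(0)
  writeBin(as.integer(data_int16), con, size = 2, endian = "little")
  invisible(path)
}

# Rectangular mask voxelized directly from the analytic box, optionally
# under a known rigid transform: both members of a test pair are then ideal
# voxelizations of congruent continuous shapes.
analytic_box_mask <- function(g, ctr, size, transform = NULL,
                              method = "target") {
  pts <- brainblocks:::grid_world_coords(g)
  if (!is.null(transform)) {
    m <- solve(rigid_matrix(transform))
    pts <- cbind(pts, 1) %*% t(m[1:3, ])
  }
  inside <- abs(pts[, 1] - ctr[1]) < size[1] / 2 &
            abs(pts[, 2] - ctr[2]) < size[2] / 2 &
            abs(pts[, 3] - ctr[3]) < size[3] / 2
  bb_mask(array(as.numeric(inside), dim = g$shape), g, method = method)
}

# Residual angle (degrees) between a recovered and a true rotation.
rotation_error_deg <- function(rot_found, rot_true) {
  Rerr <- brainblocks:::rotation_matrix(rot_found) %*%
    t(brainblocks:::rotation_matrix(rot_true))
  acos(min(1, (sum(diag(Rerr)) - 1) / 2)) * 180 / pi
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_private_seed <- function(seed, expr) brainblocks:::with_seed(seed, expr)

# Memoized expensive shared fixtures (built once per test run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# The default-condition study cohort: n = 20 subjects, default landmark
# jitter (sigma_AP = 6 mm), master seed 1.
default_cohort20 <- function() cached("cohort20", make_cohort(n = 20, seed = 1))

# Small phantom on a coarse grid for fast pipeline tests.
small_spec <- function() phantom_spec(shape = c(48L, 60L, 48L), voxel_mm = 4)
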