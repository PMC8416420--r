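test_that("volumes round-trip through NIfTI, including oblique affines", {
  g <- rotated_grid(shape = c(6, 7, 8), voxel = 1.5, deg = 17)
  set.seed(11)
  v <- bb_volume(array(sample(0:9, 336, replace = TRUE), dim = c(6, 7, 8)), g)
  p <- file.path(tempdir(), "rt.nii.gz")
  write_volume(v, p, datatype = "int16")
  v2 <- read_volume(p)
  expect_identical(as.vector(v2$data), as.vector(as.numeric(v$data)))
  expect_lt(max(abs(v2$grid$affine - g$affine)), 1e-5)
})

test_that("4D volumes store the repetition time and are rejected by the 3D reader", {
  g <- test_grid(c(4, 5, 6), voxel = 2)
  ts <- bb_volume4d(array(rnorm(4 * 5 * 6 * 7), dim = c(4, 5, 6, 7)), g, tr = 2.5)
  p <- file.path(tempdir(), "ts.nii.gz")
  write_volume(ts, p)
  back <- read_volume4d(p)
  expect_equal(back$tr, 2.5, tolerance = 1e-6)
  expect_equal(dim(back$data)[4], 7L)
  expect_error(read_volume(p), "expected 3D")
  expect_error(read_volume4d(file.path(tempdir(), "rt.nii.gz")), "expected 4D")
})

test_that("on-disk slope/intercept scaling is applied at load", {
  # oracle file written byte-by-byte, independent of any NIfTI library:
  # stored int16 value 3 with slope 2, intercept 1 must load as 2*3 + 1 = 7
  p <- file.path(tempdir(), "scl.nii")
  write_nifti_raw(p, c(3L), dims = c(1, 1, 1), slope = 2, inter = 1)
  v <- read_volume(p)
  expect_equal(as.vector(v$data), 7)
})

test_that("writing to a nonexistent directory fails", {
  g <- test_grid(c(3, 3, 3))
  v <- bb_volume(array(1, dim = c(3, 3, 3)), g)
  expect_error(write_volume(v, file.path(tempdir(), "no_such_dir", "x.nii")),
               "directory")
})

test_that("world/voxel conversion matches hand-solved cases and inverts exactly", {
  gi <- bb_grid(c(10, 10, 10), diag(4))
  expect_equal(as.vector(world_to_voxel(gi, c(3, 4, 5))), c(3, 4, 5))
  g2 <- test_grid(c(20, 20, 20), voxel = 2, origin = c(-10, -10, -10))
  expect_equal(as.vector(world_to_voxel(g2, c(0, 0, 0))), c(5, 5, 5))
  g3 <- rotated_grid(c(12, 12, 12), voxel = 1.3, deg = 33)
  set.seed(2)
  pts <- matrix(rnorm(300, sd = 15), ncol = 3)
  back <- voxel_to_world(g3, world_to_voxel(g3, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("grid invariants are enforced", {
  expect_error(bb_grid(c(2, 2), diag(4)), "3 positive")
  bad <- diag(4); bad[4, 1] <- 1
  expect_error(bb_grid(c(2, 2, 2), bad), "last row")
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(bb_grid(c(2, 2, 2), sing), "invertible")
  expect_error(bb_volume(array(c(1, NA), dim = c(2, 1, 1)),
                         test_grid(c(2, 1, 1))), "non-finite")
})

test_that("resampling honors identity, value sets, constants and linear fields", {
  g <- test_grid(c(10, 12, 14), voxel = 2)
  set.seed(3)
  v <- bb_volume(array(rnorm(10 * 12 * 14), dim = c(10, 12, 14)), g)
  for (m in c("nearest", "trilinear"))
    expect_equal(resample_to_grid(v, g, m)$data, v$data, tolerance = 1e-12)

  mask <- bb_volume(array(as.numeric(runif(10 * 12 * 14) > 0.5),
                          dim = c(10, 12, 14)), g)
  up <- test_grid(c(20, 24, 28), voxel = 1,
                  origin = voxel_to_world(g, c(0, 0, 0)) - 0.5)
  expect_true(all(resample_to_grid(mask, up, "nearest")$data %in% c(0, 1)))

  const <- bb_volume(array(7, dim = c(10, 12, 14)), g)
  inner <- test_grid(c(6, 6, 6), voxel = 1.5,
                     origin = voxel_to_world(g, c(2, 2, 2)))
  expect_equal(unique(as.vector(resample_to_grid(const, inner, "trilinear")$data)), 7)

  # trilinear is exact on an affine-linear intensity field in the interior
  w <- brainblocks:::grid_world_coords(g)
  lin <- bb_volume(array(2 + 0.3 * w[, 1] - 0.1 * w[, 2] + 0.05 * w[, 3],
                         dim = c(10, 12, 14)), g)
  tgt <- test_grid(c(7, 7, 7), voxel = 1.1,
                   origin = voxel_to_world(g, c(3, 3, 3)) + 0.37)
  got <- resample_to_grid(lin, tgt, "trilinear")
  wt <- brainblocks:::grid_world_coords(tgt)
  expected <- 2 + 0.3 * wt[, 1] - 0.1 * wt[, 2] + 0.05 * wt[, 3]
  expect_lt(max(abs(as.vector(got$data) - expected)), 1e-4)
})

test_that("NaN voxels are rejected or zero-filled per configuration", {
  g <- test_grid(c(2, 2, 2))
  arr <- array(c(1, NaN, rep(1, 6)), dim = c(2, 2, 2))
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(g$affine, code = 2L)
  p <- file.path(tempdir(), "nan.nii.gz")
  RNifti::writeNifti(img, p)
  expect_error(read_volume(p, nan = "error"), "non-finite")
  v <- read_volume(p, nan = "zero")
  expect_equal(sum(v$data), 7)
})
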