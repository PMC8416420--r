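test_that("identity and single-voxel translations act exactly on masks", {
  g <- test_grid(c(30, 30, 30), voxel = 2)
  st <- make_slice_stack(g, 4)
  m <- place_block(st, 4, c(0, 0), c(20, 16))
  mid <- apply_transform_to_mask(m, rigid_transform())
  expect_identical(mid$data, m$data + 0)
  # translation by exactly one voxel pitch: same count, shifted index
  sh <- apply_transform_to_mask(m, rigid_transform(translation = c(2, 0, 0)))
  expect_equal(sum(sh$data), sum(m$data))
  expect_identical(sh$data[2:30, , ], m$data[1:29, , ] + 0)
})

test_that("composition happens before resampling", {
  g <- test_grid(c(20, 20, 20), voxel = 2)
  st <- make_slice_stack(g, 4)
  m <- place_block(st, 3, c(0, 0), c(12, 12))
  fwd <- compose_affines(rigid_transform(translation = c(1, 0, 0)),
                         rigid_transform(translation = c(-1, 0, 0)))
  expect_lt(max(abs(fwd - diag(4))), 1e-12)
  moved <- apply_transform_to_mask(m, fwd)
  expect_identical(moved$data, m$data + 0)
})

test_that("percent overlap matches brute-force voxel counting", {
  g <- test_grid(c(20, 20, 20), voxel = 1, origin = c(0, 0, 0))
  ref <- array(0, dim = c(20, 20, 20)); ref[1:10, 1:10, 1:2] <- 1   # 200 voxels
  sam <- array(0, dim = c(20, 20, 20)); sam[1:5, 1:10, 1:2] <- 1    # covers 100
  sam[1:5, 1:10, 3:4] <- 1                                          # outside ref
  rm_ <- bb_mask(ref, g); sm <- bb_mask(sam, g)
  expect_equal(percent_overlap(sm, rm_), 100 * 100 / 200)
  expect_equal(percent_overlap(sm, rm_, "sample"), 100 * 100 / 200)
  expect_equal(percent_overlap(sm, rm_, "union"), 100 * 100 / 300)
  expect_equal(percent_overlap(sm, rm_, "dice"), 100 * 200 / 400)
  expect_equal(percent_overlap(rm_, rm_), 100)
  dis <- array(0, dim = c(20, 20, 20)); dis[15:20, 15:20, 15:20] <- 1
  expect_equal(percent_overlap(bb_mask(dis, g), rm_), 0)
})

test_that("percent overlap is invariant under simultaneous rigid motion", {
  g <- test_grid(c(50, 50, 50), voxel = 1)
  st <- make_slice_stack(g, 4)
  a <- place_block(st, 5, c(0, 0), c(20, 16))
  b <- place_block(st, 6, c(4, 3), c(20, 16))
  base <- percent_overlap(a, b)
  tr <- rigid_transform(rotation = c(0.1, 0.15, -0.12),
                        translation = c(3, -2, 4), center = mask_centroid(b))
  pa <- percent_overlap(apply_transform_to_mask(a, tr),
                        apply_transform_to_mask(b, tr))
  expect_lt(abs(pa - base), 2)
})

test_that("AP slab search equals exhaustive enumeration (oracle identity)", {
  set.seed(7)
  g <- test_grid(c(24, 40, 24), voxel = 2)
  st <- make_slice_stack(g, 4)
  for (case in 1:12) {
    s_slab <- sample(2:(st$n_slabs - 3), 1)
    r_slab <- sample(2:(st$n_slabs - 3), 1)
    off <- runif(2, -6, 6)
    s <- place_block(st, s_slab, c(0, 0), c(24, 20))
    r <- place_block(st, r_slab, off, c(24, 20), method = "reference")
    res <- ap_slab_search(s, r, st)
    # oracle: shift the mask array by whole slabs (2 voxels per slab here)
    ks <- (-s$slab_index):(st$n_slabs - 1 - s$slab_index)
    ov <- vapply(ks, function(k) {
      shifted <- array(0, dim = dim(s$data))
      src_j <- seq_len(40) - 2 * k
      ok <- src_j >= 1 & src_j <= 40
      shifted[, which(ok), ] <- s$data[, src_j[ok], ]
      sum(shifted * r$data)
    }, numeric(1))
    expect_equal(sum(res$moved_mask$data * r$data), max(ov))
    expect_equal(res$percent_overlap, 100 * max(ov) / sum(r$data))
    # tie-break: smallest |k|, then smallest k
    best <- ks[ov == max(ov)]
    expect_equal(res$slab_offset, best[order(abs(best), best)][1])
  }
})

test_that("AP search handles the trivial and degenerate cases", {
  g <- test_grid(c(24, 40, 24), voxel = 2)
  st <- make_slice_stack(g, 4)
  s <- place_block(st, 4, c(0, 0), c(20, 16))
  same <- ap_slab_search(s, s, st)
  expect_equal(same$slab_offset, 0L)
  expect_equal(same$percent_overlap, 100)
  # in-plane disjoint at every slab: overlap 0, k = 0 by tie-break
  r <- place_block(st, 6, c(-18, -18), c(8, 8), method = "reference")
  far <- ap_slab_search(s, r, st)
  expect_equal(far$percent_overlap, 0)
  expect_equal(far$slab_offset, 0L)
  expect_equal(same$moved_mask$method, "guided")
})

test_that("displacement fields act as pull maps and match equivalent translations", {
  g <- test_grid(c(20, 24, 20), voxel = 2)
  st <- make_slice_stack(g, 4)
  m <- place_block(st, 3, c(0, 0), c(12, 10))
  # constant field d = (2, 0, 0): pull x -> x + d equals forward shift by -2
  vec <- array(0, dim = c(g$shape, 3)); vec[, , , 1] <- 2
  f <- displacement_field(vec, g)
  got <- apply_transform_to_mask(m, f, convention = "pull")
  want <- apply_transform_to_mask(m, rigid_transform(translation = c(-2, 0, 0)))
  expect_identical(got$data, want$data)
  expect_error(apply_transform_to_mask(m, f, convention = "forward"), "pull")

  p <- file.path(tempdir(), "disp.nii.gz")
  write_dispfield(f, p)
  back <- read_dispfield(p)
  expect_equal(back$vectors, f$vectors, tolerance = 1e-6)
  expect_lt(max(abs(back$grid$affine - g$affine)), 1e-5)
})

test_that("affine transforms serialize as plain text", {
  tr <- rigid_transform(rotation = c(0.05, -0.1, 0.2),
                        translation = c(1.5, -2.25, 3),
                        center = c(4, 5, 6))
  p <- file.path(tempdir(), "aff.txt")
  write_affine_text(tr, p)
  m <- read_affine_text(p)
  expect_equal(m, rigid_matrix(tr), tolerance = 1e-12)
})
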