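test_that("the phantom template is deterministic with protocol-sized targets", {
  spec <- small_spec()
  tb <- make_template(spec)
  tb2 <- make_template(spec)
  expect_identical(tb$volume$data, tb2$volume$data)
  expect_identical(tb$region_centers, tb2$region_centers)

  expect_equal(length(tb$targets), 4L)
  vox_mm3 <- prod(grid_spacing(tb$grid))
  for (tg in tb$targets) {
    vol <- sum(tg$data) * vox_mm3
    shell <- 2 * (38 * 32 + 38 * 4 + 32 * 4) * spec$voxel_mm
    expect_lt(abs(vol - 38 * 32 * 4), shell)
    expect_equal(tg$method, "target")
  }

  # brain volume close to the analytic ellipsoid volume
  analytic <- 4 / 3 * pi * prod(spec$semi_axes_mm)
  expect_lt(abs(sum(tb$brain) * vox_mm3 - analytic) / analytic, 0.1)

  # planted communities partition the regions into AP bands
  expect_equal(sort(unique(tb$communities)), 1:spec$n_communities)
  band_y <- vapply(1:spec$n_communities, function(k)
    mean(tb$region_centers[tb$communities == k, 2]), numeric(1))
  expect_true(all(diff(band_y) > 0))
})

test_that("a zero-deformation subject reproduces the template exactly", {
  tb <- make_template(small_spec())
  tr0 <- subject_truth("sub-00", seed = 5, sigma_ap_mm = 0,
                       sigma_inplane_mm = 0, sigma_place_mm = 0,
                       rot_sd_deg = 0, trans_sd_mm = 0, warp_amp_mm = 0)
  s0 <- make_subject(tb, tr0, anat = TRUE)
  expect_equal(max(abs(s0$volume$data - tb$volume$data)), 0, tolerance = 1e-9)
  for (roi in names(tb$targets)) {
    expect_identical(s0$reference[[roi]]$data, tb$targets[[roi]]$data + 0)
    expect_equal(percent_overlap(s0$subject_specific[[roi]],
                                 s0$reference[[roi]]), 100)
  }
  expect_equal(s0$landmark_true_mm, tb$landmark_mm)
})

test_that("a pure translation moves reference blocks by whole slabs", {
  tb <- make_template(small_spec())
  tr <- subject_truth("sub-t", seed = 6, sigma_ap_mm = 0, sigma_inplane_mm = 0,
                      sigma_place_mm = 0, rot_sd_deg = 0, trans_sd_mm = 0,
                      warp_amp_mm = 0)
  tr$rigid <- rigid_transform(translation = c(0, 8, 0))
  s <- make_subject(tb, tr)
  for (roi in c("MFG", "V1")) {
    d <- mask_centroid(s$reference[[roi]]) - mask_centroid(tb$targets[[roi]])
    expect_equal(unname(d), c(0, 8, 0), tolerance = 0.6)
    # two slabs anterior of the target slab
    expect_equal(slab_of_point(tb$stack, mask_centroid(s$reference[[roi]])),
                 tb$targets[[roi]]$slab_index + 2L)
  }
  # the landmark moves with the brain, so zero jitter keeps sampling aligned
  expect_equal(percent_overlap(s$subject_specific$MSTG, s$reference$MSTG), 100)
})

test_that("reference masks equal the targets mapped by the true transform", {
  tb <- make_template(small_spec())
  tr <- subject_truth("sub-w", seed = 8)
  s <- make_subject(tb, tr)
  for (roi in c("MFG", "IPL")) {
    ref <- s$reference[[roi]]
    # oracle: pull every reference voxel center back to template space and
    # test membership in the target's world box
    vox <- arrayInd(which(ref$data == 1), dim(ref$data)) - 1
    u <- truth_pull(tr, voxel_to_world(ref$grid, vox))
    tg <- tb$targets[[roi]]
    bb <- brainblocks:::mask_world_bbox(tg)
    half <- grid_spacing(tb$grid) / 2
    inside <- u[, 1] >= bb$lo[1] - half[1] & u[, 1] <= bb$hi[1] + half[1] &
              u[, 2] >= bb$lo[2] - half[2] & u[, 2] <= bb$hi[2] + half[2] &
              u[, 3] >= bb$lo[3] - half[3] & u[, 3] <= bb$hi[3] + half[3]
    expect_gte(mean(inside), 0.99)
  }
})

test_that("landmark jitter displaces the sampled slab as the tail arithmetic predicts", {
  # P(|N(0,6)| > 2) ~ 0.74, so with 4 mm slabs most subjects sample a slab
  # other than the one the reference block occupies
  co <- default_cohort20()
  mismatch <- vapply(co$subjects, function(s) {
    ss_slab <- s$subject_specific$MSTG$slab_index
    ref_slab <- slab_of_point(s$stack, mask_centroid(s$reference$MSTG))
    ss_slab != ref_slab
  }, logical(1))
  expect_gte(mean(mismatch), 0.3)
})

test_that("folding warps are rejected", {
  tr <- subject_truth("sub-f", seed = 9, warp_amp_mm = 3, warp_lambda_mm = 80)
  tr$warp$amp <- c(40, 40, 40)  # gradient > 1: not invertible
  expect_error(make_subject(make_template(small_spec()), tr), "folding")
})

test_that("BOLD simulation carries the planted covariance", {
  spec <- small_spec()
  tb <- make_template(spec)
  tr0 <- subject_truth("sub-b", seed = 11, sigma_ap_mm = 0,
                       sigma_inplane_mm = 0, sigma_place_mm = 0,
                       rot_sd_deg = 0, trans_sd_mm = 0, warp_amp_mm = 0)
  s <- make_subject(tb, tr0)

  # noiseless: all voxels of one region share one series
  bs <- bold_spec(n_timepoints = 20, noise_sd = 0, func_voxel_mm = 8, seed = 3)
  b0 <- simulate_bold(s, tb, bs)
  mat <- matrix(b0$ts$data, nrow = prod(b0$grid$shape))
  vb <- which(rowSums(mat != 0) > 0)
  reg1 <- vb[b0$membership[seq_along(vb)] == b0$membership[1]][1:2]
  expect_equal(mat[reg1[1], ], mat[reg1[2], ])

  # law of large numbers: empirical region correlations approach the
  # planted matrix (noiseless, unsmoothed, long series)
  b1 <- simulate_bold(s, tb, bold_spec(n_timepoints = 2000, noise_sd = 0,
                                       smooth_sd_tr = 0, func_voxel_mm = 8,
                                       seed = 4))
  reg_ts <- brainblocks:::region_timeseries(b1$ts, b1$regions)
  ok <- which(!b1$regions$empty)
  emp <- stats::cor(reg_ts[, ok])
  expect_lt(mean(abs(emp - b1$cov[ok, ok])), 0.03)
  expect_lt(max(abs(emp - b1$cov[ok, ok])), 0.15)

  # determinism
  b2 <- simulate_bold(s, tb, bs)
  expect_identical(b0$ts$data, b2$ts$data)
})

test_that("cohorts are reproducible and serialize with a verifiable manifest", {
  spec <- small_spec()
  d <- file.path(tempdir(), "cohort_out")
  unlink(d, recursive = TRUE)
  co <- make_cohort(n = 2, seed = 5, spec = spec, dir = d)
  co2 <- make_cohort(n = 2, seed = 5, spec = spec)
  expect_identical(co$subjects[[1]]$truth, co2$subjects[[1]]$truth)
  expect_identical(co$subjects[[2]]$subject_specific$V1$data,
                   co2$subjects[[2]]$subject_specific$V1$data)
  expect_true(verify_cohort(d))
  expect_true(file.exists(file.path(d, "template.nii.gz")))
  expect_true(file.exists(file.path(d, "truth", "sub-01.json")))
  # truth JSON regenerates byte-identically
  j1 <- readLines(file.path(d, "truth", "sub-01.json"))
  d2 <- file.path(tempdir(), "cohort_out2")
  unlink(d2, recursive = TRUE)
  make_cohort(n = 2, seed = 5, spec = spec, dir = d2)
  expect_identical(j1, readLines(file.path(d2, "truth", "sub-01.json")))
  expect_error(make_cohort(n = 0), "at least 1")
})
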