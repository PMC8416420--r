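test_that("overlap count maps equal the sum of the individual masks", {
  g <- test_grid(c(16, 16, 16), voxel = 1, origin = c(0, 0, 0))
  set.seed(5)
  masks <- lapply(1:3, function(i) {
    a <- array(0, dim = c(16, 16, 16))
    lo <- sample(1:8, 3)
    a[lo[1]:(lo[1] + 6), lo[2]:(lo[2] + 6), lo[3]:(lo[3] + 6)] <- 1
    bb_mask(a, g)
  })
  map <- overlap_count_map(masks)
  brute <- masks[[1]]$data + masks[[2]]$data + masks[[3]]$data
  expect_identical(map$counts + 0, brute + 0)
  expect_equal(sum(map$counts), sum(vapply(masks, function(m) sum(m$data), 0)))
  expect_true(all(map$counts >= 0 & map$counts <= 3))

  same <- overlap_count_map(list(masks[[1]], masks[[1]], masks[[1]], masks[[1]]))
  expect_true(all(same$counts[masks[[1]]$data == 1] == 4))
  expect_true(all(same$counts[masks[[1]]$data == 0] == 0))

  d1 <- array(0, dim = c(16, 16, 16)); d1[1:3, 1:3, 1:3] <- 1
  d2 <- array(0, dim = c(16, 16, 16)); d2[10:12, 10:12, 10:12] <- 1
  expect_equal(max(overlap_count_map(list(bb_mask(d1, g), bb_mask(d2, g)))$counts), 1)

  g2 <- test_grid(c(16, 16, 16), voxel = 2)
  expect_error(overlap_count_map(list(masks[[1]], bb_mask(d1, g2))), "grid")
})

test_that("overlap histograms tabulate degrees of overlap over the union", {
  g <- test_grid(c(12, 12, 12), voxel = 1, origin = c(0, 0, 0))
  # two half-overlapping equal-size masks: k=1 66.7%, k=2 33.3% of union
  a <- array(0, dim = c(12, 12, 12)); a[1:8, 1:4, 1:4] <- 1
  b <- array(0, dim = c(12, 12, 12)); b[5:12, 1:4, 1:4] <- 1
  map <- overlap_count_map(list(bb_mask(a, g), bb_mask(b, g)))
  h <- overlap_histogram(map)
  expect_equal(h$pct[h$k == 1], 200 / 3, tolerance = 1e-9)
  expect_equal(h$pct[h$k == 2], 100 / 3, tolerance = 1e-9)
  expect_equal(sum(h$pct), 100, tolerance = 1e-9)

  hw <- overlap_histogram(map, "whole_map")
  expect_equal(hw$n_voxels, h$n_voxels)
  expect_equal(sum(hw$pct), 100 * sum(h$n_voxels) / prod(g$shape),
               tolerance = 1e-9)

  same <- overlap_count_map(list(bb_mask(a, g), bb_mask(a, g), bb_mask(a, g)))
  hs <- overlap_histogram(same)
  expect_equal(hs$pct[hs$k == 3], 100)

  empty <- structure(list(grid = g, counts = array(0L, dim = g$shape),
                          n_subjects = 3L, roi_label = "x"),
                     class = "bb_overlap_map")
  expect_equal(nrow(overlap_histogram(empty)), 0)
})

test_that("max-overlap summaries are consistent with the histogram", {
  g <- test_grid(c(12, 12, 12), voxel = 1, origin = c(0, 0, 0))
  a <- array(0, dim = c(12, 12, 12)); a[1:4, 1:4, 1:4] <- 1
  same <- overlap_count_map(rep(list(bb_mask(a, g)), 35))
  s1 <- max_overlap_summary(same)
  expect_equal(s1$max_k, 35L)
  expect_equal(s1$pct_at_max, 100)

  d1 <- array(0, dim = c(12, 12, 12)); d1[1:2, 1:2, 1:2] <- 1
  d2 <- array(0, dim = c(12, 12, 12)); d2[9:10, 9:10, 9:10] <- 1
  s2 <- max_overlap_summary(overlap_count_map(list(bb_mask(d1, g),
                                                   bb_mask(d2, g))))
  expect_equal(s2$max_k, 1L)
  expect_equal(s2$pct_k_ge_2, 0)

  # 5-subject cohort with known nested intersections along x
  masks <- lapply(1:5, function(i) {
    m <- array(0, dim = c(12, 12, 12)); m[1:(2 * i), 1:2, 1:2] <- 1
    bb_mask(m, g)
  })
  s3 <- max_overlap_summary(overlap_count_map(masks))
  # union 10*4=40 voxels; k=5 on x 1:2 -> 8 voxels
  expect_equal(s3$max_k, 5L)
  expect_equal(s3$pct_at_max, 100 * 8 / 40)
  expect_equal(s3$pct_k_ge_2, 100 * 32 / 40)
})

test_that("accuracy tables validate completeness and compute textbook summaries", {
  rec <- expand.grid(subject_id = c("s1", "s2", "s3"),
                     roi_label = "MFG",
                     method = c("subject_specific", "guided", "optimal"),
                     stringsAsFactors = FALSE)
  rec$percent_overlap <- 100
  t1 <- accuracy_table(rec)
  expect_true(all(t1$summary$mean == 100))
  expect_true(all(t1$summary$sd == 0))

  rec2 <- rec
  rec2$percent_overlap <- rep(c(0, 50, 100), 3)
  t2 <- accuracy_table(rec2)
  expect_equal(unique(t2$summary$mean), 50)
  expect_equal(unique(t2$summary$sd), 50)
  expect_equal(unique(t2$summary$median), 50)

  expect_error(accuracy_table(rbind(rec, rec[1, ])), "duplicate")
  expect_warning(t3 <- accuracy_table(rec[-1, ]), "missing")
  expect_equal(nrow(t3$missing), 1)
  expect_error(accuracy_table(transform(rec, percent_overlap = 101)), "0, 100")
})

test_that("maps and tables serialize to NIfTI and TSV", {
  g <- test_grid(c(10, 10, 10), voxel = 2)
  a <- array(0, dim = c(10, 10, 10)); a[3:6, 3:6, 3:6] <- 1
  map <- overlap_count_map(list(bb_mask(a, g), bb_mask(a, g)))
  p <- file.path(tempdir(), "map.nii.gz")
  write_overlap_map(map, p)
  back <- read_volume(p)
  expect_equal(as.vector(back$data), as.vector(map$counts + 0))

  h <- overlap_histogram(map)
  pt <- file.path(tempdir(), "h.tsv")
  write_tsv(h, pt)
  expect_equal(utils::read.table(pt, header = TRUE, sep = "\t"), h)
})
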