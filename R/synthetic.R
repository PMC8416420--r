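# Synthetic phantom cohort with known ground truth: an ellipsoidal brain
# with a gyrified cortical ribbon on a template grid, per-subject rigid +
# smooth nonlinear deformations, a jittered anterior-commissure-like
# landmark driving block placement, and BOLD-like timeseries with a planted
# region-community covariance. Every downstream quantity (reference masks,
# landmark positions, connectivity structure) is known exactly, so the
# sampling pipeline can be validated end to end.

#' Phantom template specification
#'
#' @param shape grid shape in voxels (default 96 x 120 x 96).
#' @param voxel_mm isotropic voxel size (default 2 mm).
#' @param semi_axes_mm brain ellipsoid semi-axes (x, y, z) in mm.
#' @param ribbon_amplitude,ribbon_freq relative intensity amplitude and
#'   angular frequency of the sinusoidal gyration pattern of the cortical
#'   ribbon.
#' @param landmark_mm world position of the anterior-commissure analogue.
#' @param rois data.frame defining the true template blocks: `roi_label`,
#'   `slab_offset` (slabs between the landmark slice and the target slice),
#'   `center_x_mm`, `center_z_mm`. Defaults emulate the four standard
#'   neuropathology regions (MFG, MSTG, IPL, V1).
#' @param thickness_mm slab thickness (4 mm protocol).
#' @param block_size_mm in-plane block footprint (38 x 32 mm protocol).
#' @param region_spacing_mm lattice spacing of the synthetic region set
#'   (default gives about 264 regions, the size of the standard functional
#'   parcellation).
#' @param region_radius_mm sphere radius for region rasterization.
#' @param n_communities number of planted network communities (AP bands).
#' @param seed integer seed.
#' @return list of class `bb_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 120L, 96L), voxel_mm = 2,
                         semi_axes_mm = c(65, 80, 60),
                         ribbon_amplitude = 0.2, ribbon_freq = 6,
                         landmark_mm = c(0, 4, -2),
                         rois = default_rois(),
                         thickness_mm = 4, block_size_mm = c(38, 32),
                         region_spacing_mm = 15, region_radius_mm = 5,
                         n_communities = 6L, seed = 1L) {
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 semi_axes_mm = semi_axes_mm,
                 ribbon_amplitude = ribbon_amplitude,
                 ribbon_freq = ribbon_freq, landmark_mm = landmark_mm,
                 rois = rois, thickness_mm = thickness_mm,
                 block_size_mm = block_size_mm,
                 region_spacing_mm = region_spacing_mm,
                 region_radius_mm = region_radius_mm,
                 n_communities = as.integer(n_communities),
                 seed = as.integer(seed)),
            class = "bb_phantom_spec")
}

default_rois <- function() {
  data.frame(roi_label = c("MFG", "MSTG", "IPL", "V1"),
             slab_offset = c(6L, 0L, -10L, -16L),
             center_x_mm = c(-32, -48, -38, -8),
             center_z_mm = c(34, -14, 30, 2),
             stringsAsFactors = FALSE)
}

# Run code with a private RNG state derived from `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647L)
  code
}

# Deterministic sub-seed derivation (kept below 2^31).
sub_seed <- function(seed, tag, i = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h * 1009 + i * 7919) %% 2147483629)
}

#' Build the phantom template bundle
#'
#' Constructs the template volume (ellipsoid brain with a sinusoidally
#' gyrified cortical ribbon), its coronal slab stack, the four true target
#' blocks, the synthetic region set with planted AP-band communities, and
#' the landmark. Deterministic given the seed carried in `spec`.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `bb_template_bundle` with elements `spec`, `grid`,
#'   `volume`, `brain` (logical array), `stack`, `landmark_mm`, `targets`
#'   (named list of [bb_mask]), `roi_protocol` (per-ROI landmark offsets),
#'   `region_centers`, `communities`, `regions` (template-grid
#'   [make_sphere_regions()]).
#' @export
make_template <- function(spec = phantom_spec()) {
  sh <- spec$shape; vx <- spec$voxel_mm
  aff <- diag(c(vx, vx, vx, 1))
  aff[1:3, 4] <- -(sh - 1) * vx / 2
  g <- bb_grid(sh, aff)
  w <- grid_world_coords(g)
  ax <- spec$semi_axes_mm
  u2 <- (w[, 1] / ax[1])^2 + (w[, 2] / ax[2])^2 + (w[, 3] / ax[3])^2
  brain <- u2 <= 1
  # intensity: dim white-matter core, bright gyrified ribbon
  theta <- atan2(w[, 3], w[, 1])
  phi <- atan2(w[, 2], sqrt(w[, 1]^2 + w[, 3]^2))
  ribbon <- brain & u2 > 0.72
  vol <- numeric(nrow(w))
  vol[brain] <- 80
  vol[ribbon] <- 100 * (1 + spec$ribbon_amplitude *
                          sin(spec$ribbon_freq * theta[ribbon]) *
                          cos(spec$ribbon_freq * phi[ribbon]))
  volume <- bb_volume(array(vol, dim = sh), g)

  stack <- make_slice_stack(g, spec$thickness_mm)
  lm <- spec$landmark_mm
  lu <- (lm[1] / ax[1])^2 + (lm[2] / ax[2])^2 + (lm[3] / ax[3])^2
  if (lu > 1) stop("landmark lies outside the brain")
  ac_slab <- slab_of_point(stack, lm)

  targets <- list()
  for (i in seq_len(nrow(spec$rois))) {
    r <- spec$rois[i, ]
    cu <- (r$center_x_mm / ax[1])^2 + (r$center_z_mm / ax[3])^2
    if (cu > 1) stop("ROI center outside the brain: ", r$roi_label)
    targets[[r$roi_label]] <-
      place_block(stack, ac_slab + r$slab_offset,
                  c(r$center_x_mm, r$center_z_mm),
                  size_mm = spec$block_size_mm, roi_label = r$roi_label,
                  method = "target")
  }
  roi_protocol <- data.frame(
    roi_label = spec$rois$roi_label,
    slab_offset = spec$rois$slab_offset,
    offset_x_mm = spec$rois$center_x_mm - lm[1],
    offset_z_mm = spec$rois$center_z_mm - lm[3],
    stringsAsFactors = FALSE)

  centers <- region_lattice(ax, spec$region_spacing_mm)
  communities <- ap_band_communities(centers, spec$n_communities)
  regions <- make_sphere_regions(centers, spec$region_radius_mm, g)

  structure(list(spec = spec, grid = g, volume = volume,
                 brain = array(brain, dim = sh), stack = stack,
                 landmark_mm = lm, targets = targets,
                 roi_protocol = roi_protocol, region_centers = centers,
                 communities = communities, regions = regions),
            class = "bb_template_bundle")
}

# Cubic lattice of region centers kept strictly inside the ellipsoid (10%
# margin so rasterized spheres stay in brain).
region_lattice <- function(semi_axes, spacing) {
  mk <- function(a) { k <- floor(a / spacing); spacing * (-k:k) }
  pts <- as.matrix(expand.grid(mk(semi_axes[1]), mk(semi_axes[2]),
                               mk(semi_axes[3])))
  u2 <- (pts[, 1] / semi_axes[1])^2 + (pts[, 2] / semi_axes[2])^2 +
        (pts[, 3] / semi_axes[3])^2
  pts <- pts[u2 <= 0.81, , drop = FALSE]
  dimnames(pts) <- NULL
  pts
}

# Planted communities: contiguous anterior-posterior bands with (near)
# equal region counts.
ap_band_communities <- function(centers, k) {
  ord <- order(centers[, 2], centers[, 1], centers[, 3])
  comm <- integer(nrow(centers))
  comm[ord] <- as.integer(cut(seq_along(ord), breaks = k, labels = FALSE))
  comm
}

#' Per-subject ground-truth deformation and sampling noise
#'
#' Draws one subject's true template-to-subject rigid motion, a smooth
#' low-frequency nonlinear warp (product-of-sinusoids displacement, world
#' mm, amplitude bounded so the map stays invertible), the landmark
#' localization jitter (anisotropic: the AP component dominates, matching
#' where slice-selection errors actually arise), and per-ROI in-plane
#' placement jitter. Deterministic given `seed`.
#'
#' @param subject_id identifier string.
#' @param seed integer seed for this subject.
#' @param sigma_ap_mm SD of the AP landmark jitter (default 6 mm).
#' @param sigma_inplane_mm SD of in-plane landmark jitter (default 3 mm).
#' @param sigma_place_mm SD of per-ROI in-plane placement jitter.
#' @param rot_sd_deg,trans_sd_mm SDs of the true rigid rotation (per axis,
#'   degrees) and translation (per axis, mm).
#' @param warp_amp_mm maximum amplitude of the nonlinear warp (mm).
#' @param warp_lambda_mm spatial wavelength of the warp (mm).
#' @param n_rois number of ROIs needing placement jitter.
#' @return list of class `bb_subject_truth`.
#' @export
subject_truth <- function(subject_id, seed, sigma_ap_mm = 6,
                          sigma_inplane_mm = 3, sigma_place_mm = 2,
                          rot_sd_deg = 2, trans_sd_mm = 3,
                          warp_amp_mm = 3, warp_lambda_mm = 80,
                          n_rois = 4L) {
  with_seed(seed, {
    rot <- pmin(pmax(stats::rnorm(3, 0, rot_sd_deg), -3 * rot_sd_deg),
                3 * rot_sd_deg) * pi / 180
    tra <- pmin(pmax(stats::rnorm(3, 0, trans_sd_mm), -3 * trans_sd_mm),
                3 * trans_sd_mm)
    amp <- pmin(pmax(stats::rnorm(3, 0, warp_amp_mm / 2), -warp_amp_mm),
                warp_amp_mm)
    phases <- matrix(stats::runif(9, 0, 2 * pi), 3, 3)
    jit <- c(stats::rnorm(1, 0, sigma_inplane_mm),
             stats::rnorm(1, 0, sigma_ap_mm),
             stats::rnorm(1, 0, sigma_inplane_mm))
    place <- matrix(stats::rnorm(2 * n_rois, 0, sigma_place_mm), n_rois, 2)
    structure(list(subject_id = subject_id, seed = as.integer(seed),
                   rigid = rigid_transform(rotation = rot, translation = tra),
                   warp = list(amp = amp, phases = phases,
                               lambda = warp_lambda_mm),
                   landmark_jitter = jit, placement_jitter = place),
              class = "bb_subject_truth")
  })
}

# Analytic warp displacement (template space, mm).
warp_displacement <- function(warp, u) {
  s <- 2 * pi / warp$lambda
  out <- matrix(0, nrow(u), 3)
  for (c_ in 1:3)
    out[, c_] <- warp$amp[c_] *
      sin(s * u[, 1] + warp$phases[c_, 1]) *
      sin(s * u[, 2] + warp$phases[c_, 2]) *
      sin(s * u[, 3] + warp$phases[c_, 3])
  out
}

#' Evaluate a subject's true transform
#'
#' `truth_pull()` maps subject-space world points to template-space points
#' (the direction used to resample template data into the subject);
#' `truth_push()` is its exact inverse (fixed-point solved), mapping
#' template points into the subject.
#'
#' @param truth a [subject_truth()].
#' @param points N x 3 world mm.
#' @return N x 3 world mm.
#' @export
truth_pull <- function(truth, points) {
  pts <- as_points(points)
  u <- apply_affine_points(invert_affine(truth$rigid), pts)
  u + warp_displacement(truth$warp, u)
}

#' @rdname truth_pull
#' @export
truth_push <- function(truth, points) {
  x <- as_points(points)
  u <- x
  for (i in 1:30) {
    u_new <- x - warp_displacement(truth$warp, u)
    if (max(abs(u_new - u)) < 1e-10) { u <- u_new; break }
    u <- u_new
  }
  apply_affine_points(rigid_matrix(truth$rigid), u)
}

# Spot-check invertibility: finite-difference Jacobian determinant of the
# pull map at a coarse lattice of points must stay positive.
check_no_folds <- function(truth, grid) {
  lo <- voxel_to_world(grid, c(0, 0, 0))
  hi <- voxel_to_world(grid, grid$shape - 1L)
  pts <- as.matrix(expand.grid(seq(min(lo[1], hi[1]), max(lo[1], hi[1]), length.out = 5),
                               seq(min(lo[2], hi[2]), max(lo[2], hi[2]), length.out = 5),
                               seq(min(lo[3], hi[3]), max(lo[3], hi[3]), length.out = 5)))
  h <- 0.5
  for (i in seq_len(nrow(pts))) {
    J <- matrix(0, 3, 3)
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- h
      J[, ax] <- (truth_pull(truth, pts[i, ] + e) -
                  truth_pull(truth, pts[i, ] - e)) / (2 * h)
    }
    if (det(J) <= 0) stop("warp too large: folding detected")
  }
  invisible(TRUE)
}

#' Materialize one phantom subject
#'
#' The subject's anatomy is the template resampled through the composed
#' true transform; the reference blocks are the target blocks mapped by the
#' same transform (the synthetic stand-in for a perfect nonlinear
#' registration); the subject-specific blocks are placed on the subject's
#' own slab stack from the jittered landmark via the sampling protocol
#' (per-ROI slab and in-plane offsets), with in-plane placement jitter.
#'
#' @param template a [make_template()] bundle.
#' @param truth a [subject_truth()].
#' @param anat also resample the full anatomical volume (slowest part;
#'   not needed for overlap analyses).
#' @return list of class `bb_subject_bundle`: `subject_id`, `truth`,
#'   `volume` (or `NULL`), `grid`, `stack`, `landmark_true_mm`,
#'   `landmark_jittered_mm`, `reference` and `subject_specific`
#'   (named lists of [bb_mask]).
#' @export
make_subject <- function(template, truth, anat = FALSE) {
  g <- template$grid
  check_no_folds(truth, g)
  pull_fn <- function(p) truth_pull(truth, p)

  volume <- NULL
  if (anat) {
    vox <- world_to_voxel(g, pull_fn(grid_world_coords(g)))
    volume <- bb_volume(array(interp_at_voxel(template$volume$data, vox),
                              dim = g$shape), g)
  }

  amax <- sum(abs(truth$warp$amp)) + 1e-3
  reference <- lapply(template$targets, function(tg) {
    bb <- mask_world_bbox(tg)
    corners <- as.matrix(expand.grid(c(bb$lo[1], bb$hi[1]),
                                     c(bb$lo[2], bb$hi[2]),
                                     c(bb$lo[3], bb$hi[3])))
    tc <- truth_push(truth, corners)
    bbox <- list(lo = apply(tc, 2, min) - amax, hi = apply(tc, 2, max) + amax)
    data <- pull_mask_on_grid(tg, g, pull_fn, bbox)
    bb_mask(data, g, roi_label = tg$roi_label, method = "reference",
            provenance = list(subject_id = truth$subject_id))
  })

  lm_true <- as.vector(truth_push(truth, template$landmark_mm))
  lm_jit <- lm_true + truth$landmark_jitter
  stack <- make_slice_stack(g, template$spec$thickness_mm)
  prot <- template$roi_protocol
  subject_specific <- list()
  for (i in seq_len(nrow(prot))) {
    subject_specific[[prot$roi_label[i]]] <- landmark_anchored_block(
      stack, lm_jit,
      c(prot$offset_x_mm[i], prot$offset_z_mm[i]) + truth$placement_jitter[i, ],
      size_mm = template$spec$block_size_mm,
      slab_offset = prot$slab_offset[i],
      roi_label = prot$roi_label[i], method = "subject_specific",
      provenance = list(subject_id = truth$subject_id))
  }

  structure(list(subject_id = truth$subject_id, truth = truth,
                 volume = volume, grid = g, stack = stack,
                 landmark_true_mm = lm_true, landmark_jittered_mm = lm_jit,
                 reference = reference,
                 subject_specific = subject_specific),
            class = "bb_subject_bundle")
}

#' BOLD simulation specification
#'
#' @param n_timepoints number of volumes (default 240).
#' @param tr repetition time in seconds (default 2.5).
#' @param rho_in,rho_out within/between community correlations of the
#'   planted region covariance (defaults 0.6 / 0.05).
#' @param noise_sd white voxel noise SD relative to the unit-variance
#'   latent signals.
#' @param smooth_sd_tr SD (in TRs) of the Gaussian temporal smoothing
#'   applied to the latent signals.
#' @param func_voxel_mm functional voxel size (default 4 mm: resting-state
#'   acquisitions are coarser than structural scans).
#' @param seed integer seed.
#' @return list of class `bb_bold_spec`.
#' @export
bold_spec <- function(n_timepoints = 240L, tr = 2.5, rho_in = 0.6,
                      rho_out = 0.05, noise_sd = 1, smooth_sd_tr = 1,
                      func_voxel_mm = 4, seed = 1L) {
  structure(list(n_timepoints = as.integer(n_timepoints), tr = tr,
                 rho_in = rho_in, rho_out = rho_out, noise_sd = noise_sd,
                 smooth_sd_tr = smooth_sd_tr, func_voxel_mm = func_voxel_mm,
                 seed = as.integer(seed)), class = "bb_bold_spec")
}

# Planted region covariance from a community partition.
community_covariance <- function(communities, rho_in, rho_out) {
  same <- outer(communities, communities, "==")
  S <- ifelse(same, rho_in, rho_out)
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("implied region covariance is not positive definite")
  S
}

#' Simulate a BOLD-like 4D timeseries for one subject
#'
#' Latent region signals are drawn from the planted community covariance
#' (iid over time, then temporally smoothed — smoothing with a common
#' kernel leaves the cross-region correlations unchanged); every brain
#' voxel carries its nearest region's latent signal plus white noise.
#' Non-brain voxels are zero. The functional grid is coarser than the
#' structural one and shares its world frame.
#'
#' @param subject a [make_subject()] bundle.
#' @param template the [make_template()] bundle.
#' @param spec a [bold_spec()].
#' @return list of class `bb_bold_bundle`: `ts` ([bb_volume4d]), `cov`
#'   (planted region covariance), `membership` (per-brain-voxel region
#'   index), `regions` (sphere region set on the functional grid at the
#'   subject-space region centers).
#' @export
simulate_bold <- function(subject, template, spec = bold_spec()) {
  sh_t <- template$grid$shape
  vx_t <- template$spec$voxel_mm
  fshape <- as.integer(ceiling(sh_t * vx_t / spec$func_voxel_mm))
  faff <- diag(c(rep(spec$func_voxel_mm, 3), 1))
  faff[1:3, 4] <- -(fshape - 1) * spec$func_voxel_mm / 2
  fgrid <- bb_grid(fshape, faff)

  w <- grid_world_coords(fgrid)
  u <- truth_pull(subject$truth, w)          # template-space coords
  ax <- template$spec$semi_axes_mm
  inbrain <- (u[, 1] / ax[1])^2 + (u[, 2] / ax[2])^2 + (u[, 3] / ax[3])^2 <= 1
  vb <- which(inbrain)
  centers <- template$region_centers
  # nearest region center (template space) per brain voxel, in chunks
  memb <- integer(length(vb))
  c2 <- rowSums(centers^2)
  step <- 20000L
  for (s in seq(1L, length(vb), by = step)) {
    idx <- s:min(s + step - 1L, length(vb))
    # argmin ||u - c||^2 == argmax 2 u.c - ||c||^2
    score <- 2 * u[vb[idx], , drop = FALSE] %*% t(centers)
    score <- sweep(score, 2, c2)
    memb[idx] <- max.col(score, "first")
  }

  S <- community_covariance(template$communities, spec$rho_in, spec$rho_out)
  T_ <- spec$n_timepoints
  res <- with_seed(spec$seed, {
    Z <- matrix(stats::rnorm(T_ * nrow(centers)), T_)
    latent <- Z %*% chol(S)
    latent <- temporal_smooth(latent, spec$smooth_sd_tr)
    noise <- matrix(stats::rnorm(length(vb) * T_, 0, spec$noise_sd),
                    length(vb), T_)
    list(latent = latent, noise = noise)
  })
  mat <- matrix(0, prod(fshape), T_)
  mat[vb, ] <- t(res$latent)[memb, , drop = FALSE] + res$noise
  ts <- bb_volume4d(array(mat, dim = c(fshape, T_)), fgrid, spec$tr)

  centers_subj <- truth_push(subject$truth, centers)
  regions <- make_sphere_regions(centers_subj, template$spec$region_radius_mm,
                                 fgrid)
  structure(list(ts = ts, cov = S, membership = memb, regions = regions,
                 grid = fgrid, spec = spec),
            class = "bb_bold_bundle")
}

# Gaussian temporal smoothing of each column, zero-padded; a common kernel
# across columns preserves the lag-0 cross-correlation structure of iid
# rows exactly (in expectation).
temporal_smooth <- function(x, sd_tr) {
  if (sd_tr <= 0) return(x)
  r <- max(1L, ceiling(3 * sd_tr))
  k <- exp(-((-r:r)^2) / (2 * sd_tr^2)); k <- k / sum(k)
  xp <- rbind(matrix(0, r, ncol(x)), x, matrix(0, r, ncol(x)))
  out <- stats::filter(xp, k, sides = 2)
  matrix(out[(r + 1):(r + nrow(x)), ], nrow(x), ncol(x))
}

#' Generate a phantom cohort
#'
#' Builds the template once and derives `n` subjects from it with
#' independent ground-truth deformations and sampling noise, all seeded
#' from one master seed through named substreams. With `dir` set, the
#' cohort is also serialized: template and mask NIfTI volumes, per-subject
#' truth JSON, and a `manifest.tsv` with MD5 checksums.
#'
#' @param n number of subjects (the emulated study cohort size is 35;
#'   smaller cohorts are used for fast validation runs).
#' @param seed master integer seed.
#' @param spec a [phantom_spec()].
#' @param subject_args list of overrides passed to [subject_truth()]
#'   (e.g. `list(sigma_ap_mm = 0)` for a zero-jitter cohort).
#' @param anat resample full anatomical volumes (off by default).
#' @param dir optional output directory.
#' @param bold write BOLD series too (only with `dir`; series are always
#'   re-simulable from the stored seeds).
#' @param bold_args list of overrides passed to [bold_spec()].
#' @return list of class `bb_cohort`: `template`, `subjects` (list of
#'   [make_subject()] bundles), `seed`, `bold_seeds`.
#' @export
make_cohort <- function(n = 35L, seed = 1L, spec = phantom_spec(),
                        subject_args = list(), anat = FALSE, dir = NULL,
                        bold = FALSE, bold_args = list()) {
  if (n < 1) stop("n must be at least 1")
  template <- make_template(spec)
  subjects <- vector("list", n)
  bold_seeds <- integer(n)
  for (i in seq_len(n)) {
    sid <- sprintf("sub-%02d", i)
    tr_args <- c(list(subject_id = sid, seed = sub_seed(seed, "truth", i),
                      n_rois = nrow(spec$rois)), subject_args)
    truth <- do.call(subject_truth, tr_args)
    subjects[[i]] <- make_subject(template, truth, anat = anat)
    bold_seeds[i] <- sub_seed(seed, "bold", i)
  }
  cohort <- structure(list(template = template, subjects = subjects,
                           seed = as.integer(seed), bold_seeds = bold_seeds,
                           bold_args = bold_args),
                      class = "bb_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir, bold = bold)
  cohort
}

#' @export
print.bb_cohort <- function(x, ...) {
  cat(sprintf("<bb_cohort> %d subjects, %d ROIs, seed %d\n",
              length(x$subjects), length(x$template$targets), x$seed))
  invisible(x)
}

# Per-subject BOLD bundle regenerated from the stored seed.
cohort_bold <- function(cohort, i) {
  args <- c(list(seed = cohort$bold_seeds[i]), cohort$bold_args)
  simulate_bold(cohort$subjects[[i]], cohort$template,
                do.call(bold_spec, args))
}

write_cohort <- function(cohort, dir, bold = FALSE) {
  for (d in file.path(dir, c("", "subjects", "masks", "truth")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(p) files <<- c(files, p)

  add(write_volume(cohort$template$volume, file.path(dir, "template.nii.gz")))
  for (tg in cohort$template$targets)
    add(write_volume(tg, file.path(dir, "masks",
                                   sprintf("template_%s_target.nii.gz",
                                           tg$roi_label)),
                     datatype = "uint8"))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    if (!is.null(s$volume))
      add(write_volume(s$volume, file.path(dir, "subjects",
                                           paste0(s$subject_id, "_T1.nii.gz"))))
    if (bold) {
      b <- cohort_bold(cohort, i)
      add(write_volume(b$ts, file.path(dir, "subjects",
                                       paste0(s$subject_id, "_bold.nii.gz"))))
    }
    for (set in c("reference", "subject_specific"))
      for (m in s[[set]])
        add(write_volume(m, file.path(dir, "masks",
                                      sprintf("%s_%s_%s.nii.gz", s$subject_id,
                                              m$roi_label, set)),
                         datatype = "uint8"))
    tj <- s$truth
    add(local({
      p <- file.path(dir, "truth", paste0(s$subject_id, ".json"))
      jsonlite::write_json(list(
        subject_id = tj$subject_id, seed = tj$seed,
        rotation_rad = tj$rigid$rotation,
        translation_mm = tj$rigid$translation,
        warp_amp_mm = tj$warp$amp, warp_phases = tj$warp$phases,
        warp_lambda_mm = tj$warp$lambda,
        landmark_jitter_mm = tj$landmark_jitter,
        placement_jitter_mm = tj$placement_jitter,
        bold_seed = cohort$bold_seeds[i]), p, digits = NA, pretty = TRUE)
      p
    }))
  }
  manifest <- data.frame(file = sub(paste0("^", dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Verify a serialized cohort against its manifest
#'
#' @param dir cohort directory written by [make_cohort()].
#' @return TRUE invisibly; errors on any checksum mismatch.
#' @export
verify_cohort <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  sums <- tools::md5sum(file.path(dir, man$file))
  bad <- man$file[is.na(sums) | sums != man$md5]
  if (length(bad)) stop("manifest mismatch: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
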