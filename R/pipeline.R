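#' Analysis run configuration
#'
#' Bundles the protocol constants and analysis knobs shared by the pipeline
#' stages. Defaults follow the standard sampling protocol (4 mm slabs,
#' 38 x 32 mm blocks) and the permutation settings (1000 samples, top and
#' bottom 5%).
#'
#' @param thickness_mm slab thickness.
#' @param block_size_mm in-plane block footprint.
#' @param denominator overlap denominator, see [percent_overlap()].
#' @param bounds_mm,bounds_deg rigid-optimizer bounds.
#' @param n_starts rigid-optimizer multi-start count.
#' @param n_perm permutation samples.
#' @param alpha per-tail empirical threshold level.
#' @param seed integer seed for seeded stages.
#' @param rois ROI labels to analyze (`NULL` = all in the cohort).
#' @return list of class `bb_run_config`.
#' @export
run_config <- function(thickness_mm = 4, block_size_mm = c(38, 32),
                       denominator = "reference", bounds_mm = 20,
                       bounds_deg = 20, n_starts = 8L, n_perm = 1000L,
                       alpha = 0.05, seed = 1L, rois = NULL) {
  structure(list(thickness_mm = thickness_mm, block_size_mm = block_size_mm,
                 denominator = denominator, bounds_mm = bounds_mm,
                 bounds_deg = bounds_deg, n_starts = as.integer(n_starts),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), rois = rois),
            class = "bb_run_config")
}

#' Load a run configuration from YAML
#'
#' Any key of [run_config()] may appear in the file; missing keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

cohort_rois <- function(cohort, config) {
  rois <- config$rois %||% names(cohort$template$targets)
  intersect(rois, names(cohort$template$targets))
}

#' Cohort precision analysis
#'
#' Maps every subject's subject-specific block into template space through
#' the subject's (ground-truth) transform and counts per-voxel overlap
#' across subjects, per ROI — how consistently the protocol hits the same
#' template tissue. Writes one count-map NIfTI and one histogram TSV per
#' ROI plus a JSON summary when `out_dir` is given.
#'
#' @param cohort a [make_cohort()] bundle.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list per ROI: `map` ([overlap_count_map()]), `histogram`,
#'   `summary` ([max_overlap_summary()]).
#' @export
run_precision <- function(cohort, config = run_config(), out_dir = NULL) {
  tg <- cohort$template$grid
  out <- list()
  for (roi in cohort_rois(cohort, config)) {
    masks <- lapply(cohort$subjects, function(s) {
      m <- s$subject_specific[[roi]]
      truth <- s$truth
      bb <- mask_world_bbox(m)
      corners <- as.matrix(expand.grid(c(bb$lo[1], bb$hi[1]),
                                       c(bb$lo[2], bb$hi[2]),
                                       c(bb$lo[3], bb$hi[3])))
      tc <- truth_pull(truth, corners)  # template-space bbox of the mask
      amax <- sum(abs(truth$warp$amp)) + 1e-3
      bbox <- list(lo = apply(tc, 2, min) - amax,
                   hi = apply(tc, 2, max) + amax)
      data <- pull_mask_on_grid(m, tg, function(p) truth_push(truth, p), bbox)
      bb_mask(data, tg, roi_label = roi, method = "subject_specific")
    })
    map <- overlap_count_map(masks, roi_label = roi)
    hist <- overlap_histogram(map)
    smry <- max_overlap_summary(map)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_overlap_map(map, file.path(out_dir,
                                       sprintf("precision_%s_counts.nii.gz", roi)))
      write_tsv(hist, file.path(out_dir,
                                sprintf("precision_%s_histogram.tsv", roi)))
    }
    out[[roi]] <- list(map = map, histogram = hist, summary = smry)
  }
  if (!is.null(out_dir)) {
    smry <- lapply(out, function(x) x$summary)
    jsonlite::write_json(smry, file.path(out_dir, "precision_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Cohort accuracy analysis
#'
#' For every (subject, ROI): percent overlap of the subject-specific block
#' with the reference block, of the AP-slab-guided block
#' ([ap_slab_search()]), and of the rigid-body optimal block
#' ([rigid_overlap_optimize()], optional). Paired Wilcoxon signed-rank
#' tests compare guided vs subject-specific and optimal vs guided per ROI;
#' a cluster-robust Poisson regression models overlap counts against the
#' method indicator across the cohort.
#'
#' @param cohort a [make_cohort()] bundle.
#' @param config a [run_config()].
#' @param optimal run the rigid optimizer (the slowest stage).
#' @param out_dir optional output directory for TSV results.
#' @return list of class `bb_accuracy_run`: `table` ([accuracy_table()]),
#'   `wilcoxon` (per-ROI data.frame), `poisson` ([poisson_robust()]).
#' @export
run_accuracy <- function(cohort, config = run_config(), optimal = TRUE,
                         out_dir = NULL) {
  rois <- cohort_rois(cohort, config)
  rows <- list(); counts <- list()
  for (s in cohort$subjects) {
    for (roi in rois) {
      ss <- s$subject_specific[[roi]]
      ref <- s$reference[[roi]]
      res_g <- ap_slab_search(ss, ref, s$stack)
      vals <- c(subject_specific = percent_overlap(ss, ref, config$denominator),
                guided = res_g$percent_overlap)
      ints <- c(subject_specific = sum(ss$data * ref$data),
                guided = sum(res_g$moved_mask$data * ref$data))
      if (optimal) {
        # the rigid feasible set must contain the guided solution, so the
        # optimal >= guided ordering is guaranteed by construction
        bmm <- max(config$bounds_mm,
                   abs(res_g$slab_offset) * config$thickness_mm + 1)
        res_o <- rigid_overlap_optimize(ss, ref, bounds_mm = bmm,
                                        bounds_deg = config$bounds_deg,
                                        n_starts = config$n_starts,
                                        thickness_mm = config$thickness_mm,
                                        seed = config$seed)
        stopifnot(res_o$percent_overlap >= res_g$percent_overlap - 1e-9)
        vals <- c(vals, optimal = res_o$percent_overlap)
        ints <- c(ints, optimal = sum(res_o$moved_mask$data * ref$data))
      }
      for (meth in names(vals)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, roi_label = roi, method = meth,
          percent_overlap = unname(vals[meth]),
          overlap_voxels = unname(ints[meth]),
          reference_voxels = sum(ref$data), stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  methods <- c("subject_specific", "guided", if (optimal) "optimal")
  tab <- accuracy_table(records, methods = methods)

  wil <- list()
  pairs <- list(c("guided", "subject_specific"),
                if (optimal) c("optimal", "guided"))
  for (roi in rois) {
    for (pr in Filter(Negate(is.null), pairs)) {
      a <- records[records$roi_label == roi & records$method == pr[1], ]
      b <- records[records$roi_label == roi & records$method == pr[2], ]
      a <- a[order(a$subject_id), ]; b <- b[order(b$subject_id), ]
      w <- tryCatch(wilcoxon_signed_rank(a$percent_overlap, b$percent_overlap),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_, n_used = 0L,
                                             mode = "degenerate"))
      wil[[length(wil) + 1L]] <- data.frame(
        roi_label = roi, comparison = paste(pr[1], "vs", pr[2]),
        W = w$statistic, p_value = w$p_value, n_used = w$n_used,
        mode = w$mode, stringsAsFactors = FALSE)
    }
  }
  wilcoxon <- do.call(rbind, wil)

  des <- data.frame(method = stats::relevel(factor(records$method),
                                            "subject_specific"))
  if (length(unique(records$roi_label)) > 1)
    des$roi <- factor(records$roi_label)
  pois <- poisson_robust(records$overlap_voxels, records$reference_voxels,
                         design = des, cluster = records$subject_id)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tab, file.path(out_dir, "accuracy_records.tsv"))
    write_tsv(wilcoxon, file.path(out_dir, "accuracy_wilcoxon.tsv"))
    write_tsv(data.frame(term = names(pois$coefficients),
                         estimate = pois$coefficients,
                         robust_se = pois$robust_se, z = pois$z_values,
                         p = pois$p_values),
              file.path(out_dir, "accuracy_poisson.tsv"))
  }
  structure(list(table = tab, wilcoxon = wilcoxon, poisson = pois),
            class = "bb_accuracy_run")
}

#' Cohort connectivity discrepancy analysis
#'
#' Per ROI: extracts the seed mean timeseries of the subject-specific and
#' reference blocks from each subject's (re-simulated) BOLD series,
#' correlates both against every region's mean series, and tests the
#' per-region connectivity differences with the sign-flip permutation test.
#'
#' @param cohort a [make_cohort()] bundle (BOLD is re-simulated per subject
#'   from the stored seeds).
#' @param config a [run_config()].
#' @param out_dir optional output directory for per-ROI TSVs.
#' @return list per ROI: a [fc_discrepancy_analysis()] result plus the raw
#'   profile matrices `r_subject_specific`, `r_reference`.
#' @export
run_connectivity <- function(cohort, config = run_config(), out_dir = NULL) {
  rois <- cohort_rois(cohort, config)
  n <- length(cohort$subjects)
  if (n < 3) stop("need at least 3 subjects with BOLD data")
  prof_ss <- prof_ref <- stats::setNames(vector("list", length(rois)), rois)
  nreg <- nrow(cohort$template$region_centers)
  for (roi in rois) {
    prof_ss[[roi]] <- matrix(NA_real_, n, nreg)
    prof_ref[[roi]] <- matrix(NA_real_, n, nreg)
  }
  for (i in seq_len(n)) {
    b <- cohort_bold(cohort, i)
    reg_ts <- region_timeseries(b$ts, b$regions)
    s <- cohort$subjects[[i]]
    for (roi in rois) {
      seed_ss <- mean_timeseries(b$ts, s$subject_specific[[roi]])
      seed_ref <- mean_timeseries(b$ts, s$reference[[roi]])
      prof_ss[[roi]][i, ] <- fc_profile(seed_ss, reg_ts)$r
      prof_ref[[roi]][i, ] <- fc_profile(seed_ref, reg_ts)$r
    }
  }
  out <- list()
  for (roi in rois) {
    disc <- fc_discrepancy_analysis(prof_ss[[roi]], prof_ref[[roi]],
                                    n_perm = config$n_perm,
                                    alpha = config$alpha, seed = config$seed)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      tab <- cbind(disc$table,
                   x_mm = cohort$template$region_centers[, 1],
                   y_mm = cohort$template$region_centers[, 2],
                   z_mm = cohort$template$region_centers[, 3])
      write_tsv(tab, file.path(out_dir, sprintf("fc_discrepancy_%s.tsv", roi)))
    }
    out[[roi]] <- c(disc, list(r_subject_specific = prof_ss[[roi]],
                               r_reference = prof_ref[[roi]]))
  }
  out
}

#' Run the full pipeline
#'
#' Precision, accuracy, and (optionally) connectivity over one cohort.
#'
#' @param cohort a [make_cohort()] bundle.
#' @param config a [run_config()].
#' @param connectivity include the BOLD stage.
#' @param optimal include the rigid optimizer in the accuracy stage.
#' @param out_dir optional output directory.
#' @return list with elements `precision`, `accuracy`, and optionally
#'   `connectivity`.
#' @export
run_all <- function(cohort, config = run_config(), connectivity = FALSE,
                    optimal = TRUE, out_dir = NULL) {
  out <- list(precision = run_precision(cohort, config, out_dir),
              accuracy = run_accuracy(cohort, config, optimal = optimal,
                                      out_dir = out_dir))
  if (connectivity)
    out$connectivity <- run_connectivity(cohort, config, out_dir)
  out
}
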