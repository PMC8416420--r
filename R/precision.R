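#' Voxelwise overlap count map
#'
#' Counts, at each voxel of a common (template) grid, how many subjects'
#' masks cover it. The count map is the cohort precision surface: a tall
#' narrow peak means everyone sampled the same tissue, a flat spread means
#' the nominally identical block landed somewhere different in every brain.
#'
#' @param masks list of [bb_mask]s, one per subject, all on the same grid.
#' @param roi_label label stored on the map (defaults to the first mask's).
#' @return an object of class `bb_overlap_map` with fields `grid`, `counts`
#'   (integer array), `n_subjects`, `roi_label`.
#' @export
overlap_count_map <- function(masks, roi_label = NULL) {
  if (length(masks) == 0) stop("no masks supplied")
  g <- masks[[1]]$grid
  counts <- array(0L, dim = g$shape)
  for (m in masks) {
    if (!grids_equal(m$grid, g)) stop("all masks must share one grid")
    counts <- counts + as.integer(m$data)
  }
  structure(list(grid = g, counts = counts, n_subjects = length(masks),
                 roi_label = roi_label %||% masks[[1]]$roi_label),
            class = "bb_overlap_map")
}

#' @export
print.bb_overlap_map <- function(x, ...) {
  cat(sprintf("<bb_overlap_map> %s, n=%d, max count %d\n", x$roi_label,
              x$n_subjects, max(x$counts)))
  invisible(x)
}

#' Write an overlap count map as integer NIfTI
#'
#' @param map a [overlap_count_map()] result.
#' @param path output path.
#' @export
write_overlap_map <- function(map, path) {
  write_volume(bb_volume(array(as.numeric(map$counts), dim = map$grid$shape),
                         map$grid), path, datatype = "int16")
}

#' Histogram of overlap degrees
#'
#' Tabulates, for k = 1..n, how many voxels are covered by exactly k
#' subjects, and the percentage of the chosen domain they represent. The
#' default domain is the union of all masks (count >= 1), over which the
#' percentages sum to 100; `"whole_map"` uses every voxel of the grid.
#'
#' @param map a [overlap_count_map()] result.
#' @param domain `"union_of_masks"` or `"whole_map"`.
#' @return data.frame with columns `k`, `n_voxels`, `pct`.
#' @export
overlap_histogram <- function(map, domain = c("union_of_masks", "whole_map")) {
  domain <- match.arg(domain)
  n <- map$n_subjects
  tab <- tabulate(map$counts[map$counts > 0], nbins = n)
  denom <- if (domain == "union_of_masks") sum(tab) else length(map$counts)
  if (sum(tab) == 0)
    return(data.frame(k = integer(0), n_voxels = integer(0), pct = numeric(0)))
  data.frame(k = seq_len(n), n_voxels = tab,
             pct = 100 * tab / denom)
}

#' Summary of the precision surface
#'
#' @param map a [overlap_count_map()] result.
#' @return list with `max_k` (largest number of subjects sharing any voxel),
#'   `pct_at_max` (% of union voxels at that count) and `pct_k_ge_2`
#'   (% of union voxels covered by at least two subjects).
#' @export
max_overlap_summary <- function(map) {
  h <- overlap_histogram(map, "union_of_masks")
  if (nrow(h) == 0) return(list(max_k = 0L, pct_at_max = 0, pct_k_ge_2 = 0))
  kmax <- max(h$k[h$n_voxels > 0])
  list(max_k = as.integer(kmax),
       pct_at_max = h$pct[h$k == kmax],
       pct_k_ge_2 = sum(h$pct[h$k >= 2]))
}

#' Accuracy records and per-method summaries
#'
#' Validates a long table of per-(subject, ROI, method) percent overlaps and
#' computes per-(ROI, method) summary statistics: mean, unbiased SD, median
#' and IQR. Duplicated cells are an error; missing cells are reported in the
#' result, never silently dropped.
#'
#' @param records data.frame with columns `subject_id`, `roi_label`,
#'   `method`, `percent_overlap`.
#' @param methods the complete set of methods every subject must have per
#'   ROI (set to `NULL` to skip the completeness check).
#' @return list of class `bb_accuracy_table` with `records`, `summary`
#'   (data.frame: roi_label, method, n, mean, sd, median, iqr) and
#'   `missing` (data.frame of absent cells).
#' @export
accuracy_table <- function(records,
                           methods = c("subject_specific", "guided",
                                       "optimal")) {
  need <- c("subject_id", "roi_label", "method", "percent_overlap")
  if (!all(need %in% names(records))) stop("missing accuracy record columns")
  if (any(records$percent_overlap < 0 | records$percent_overlap > 100))
    stop("percent_overlap must be in [0, 100]")
  key <- interaction(records$subject_id, records$roi_label, records$method,
                     drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (subject, roi, method) rows")
  missing <- data.frame()
  if (!is.null(methods)) {
    full <- expand.grid(subject_id = unique(records$subject_id),
                        roi_label = unique(records$roi_label),
                        method = methods, stringsAsFactors = FALSE)
    have <- paste(records$subject_id, records$roi_label, records$method)
    missing <- full[!paste(full$subject_id, full$roi_label, full$method)
                    %in% have, , drop = FALSE]
    if (nrow(missing) > 0)
      warning(nrow(missing), " missing (subject, roi, method) cells")
  }
  agg <- do.call(rbind, lapply(
    split(records, list(records$roi_label, records$method), drop = TRUE),
    function(d) data.frame(roi_label = d$roi_label[1], method = d$method[1],
                           n = nrow(d),
                           mean = mean(d$percent_overlap),
                           sd = stats::sd(d$percent_overlap),
                           median = stats::median(d$percent_overlap),
                           iqr = stats::IQR(d$percent_overlap))))
  rownames(agg) <- NULL
  structure(list(records = records, summary = agg, missing = missing),
            class = "bb_accuracy_table")
}

#' @export
print.bb_accuracy_table <- function(x, ...) {
  cat("<bb_accuracy_table>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write tables as TSV
#'
#' @param x a data.frame (or [accuracy_table()] result, whose records and
#'   summary are written to `<path>` and `<path stem>_summary.tsv`).
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  if (inherits(x, "bb_accuracy_table")) {
    utils::write.table(x$records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(x$summary,
                       sub("\\.tsv$", "_summary.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
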