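# Segmentation quality metrics: voxelwise confusion counts, the five rate
# metrics, the symmetric 95th-percentile Hausdorff surface distance, and
# cohort aggregation.

#' Voxelwise confusion counts
#'
#' Brain is the positive class. Counts satisfy TP+FP+FN+TN = total voxels.
#'
#' @param pred,gt binary [volume_grid]s on the same grid.
#' @return an object of class `confusion_counts` with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion_counts <- function(pred, gt) {
  stopifnot(is_volume_grid(pred), is_volume_grid(gt))
  if (!same_grid(pred, gt))
    stop("alignment error: prediction and ground truth are on different grids",
         call. = FALSE)
  p <- pred$values > 0.5
  g <- gt$values > 0.5
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "confusion_counts")
}

#' Rate metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN), precision = TP/(TP+FP), recall = TP/(TP+FN),
#' FPR = FP/(FP+TN), FNR = FN/(FN+TP). Degenerate denominators follow fixed
#' conventions: with both masks empty, dice = precision = recall = 1 and
#' fpr = fnr = 0; an empty ground truth against a nonempty prediction gives
#' dice = 0. `recall + fnr = 1` holds exactly in all cases.
#'
#' @param counts a [confusion_counts].
#' @return tibble with columns `dice`, `precision`, `recall`, `fpr`, `fnr`.
#' @export
rate_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  dice <- if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
  precision <- if (TP + FP == 0) 1 else TP / (TP + FP)
  recall <- if (TP + FN == 0) 1 else TP / (TP + FN)
  fpr <- if (FP + TN == 0) 0 else FP / (FP + TN)
  tibble::tibble(dice = dice, precision = precision, recall = recall,
                 fpr = fpr, fnr = 1 - recall)
}

#' 95th-percentile Hausdorff surface distance (mm)
#'
#' Symmetric: the maximum of the two directed 95th-percentile distances
#' between the 6-connectivity boundary voxels of the two masks, measured
#' between voxel centres in physical units. Computed with an exact Euclidean
#' distance transform; equals the brute-force pairwise definition.
#'
#' @param pred,gt nonempty binary [volume_grid]s on the same grid.
#' @return distance in millimetres.
#' @export
hd95 <- function(pred, gt) {
  stopifnot(is_volume_grid(pred), is_volume_grid(gt))
  if (!same_grid(pred, gt))
    stop("alignment error: masks on different grids", call. = FALSE)
  d <- dim(pred$values)
  pm <- pred$values > 0.5
  gm <- gt$values > 0.5
  if (!any(pm) || !any(gm))
    stop("undefined distance: hd95 requires two nonempty masks",
         call. = FALSE)
  sp <- pred$spacing
  pb <- cpp_boundary(as.logical(pm), d[1], d[2], d[3])
  gb <- cpp_boundary(as.logical(gm), d[1], d[2], d[3])
  dist_to_g <- cpp_edt(gb, d[1], d[2], d[3], sp[1], sp[2], sp[3])
  dist_to_p <- cpp_edt(pb, d[1], d[2], d[3], sp[1], sp[2], sp[3])
  d_pg <- stats::quantile(dist_to_g[pb], 0.95, names = FALSE)
  d_gp <- stats::quantile(dist_to_p[gb], 0.95, names = FALSE)
  max(d_pg, d_gp)
}

#' All six metrics for one case
#'
#' @param pred,gt binary [volume_grid]s on the same grid.
#' @return one-row tibble: `dice`, `precision`, `recall`, `fpr`, `fnr`,
#'   `hd95_mm`.
#' @export
evaluate_case <- function(pred, gt) {
  rates <- rate_metrics(confusion_counts(pred, gt))
  h <- if (any(pred$values > 0.5) && any(gt$values > 0.5))
    hd95(pred, gt) else NA_real_
  dplyr::mutate(rates, hd95_mm = h)
}

#' Cohort summary of metric reports
#'
#' Mean and sample standard deviation (n-1; 0 for a single case) of every
#' metric, overall or per group.
#'
#' @param reports tibble of per-case metric rows (e.g. from
#'   [evaluate_fit()]), containing columns `dice`, `precision`, `recall`,
#'   `fpr`, `fnr`, `hd95_mm`.
#' @param group_labels optional vector (length `nrow(reports)`) of condition
#'   tags; when supplied, summaries are computed per group as well as
#'   overall.
#' @return tibble with columns `group`, `stat` (`"mean"`/`"sd"`), the six
#'   metrics in reporting order, and `n_cases`.
#' @export
summarize_cohort <- function(reports, group_labels = NULL) {
  met <- c("dice", "precision", "recall", "fpr", "fnr", "hd95_mm")
  if (nrow(reports) < 1) stop("no reports to summarise", call. = FALSE)
  missing <- setdiff(met, names(reports))
  if (length(missing))
    stop("reports lack metric columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  one <- function(df, label) {
    mu <- vapply(met, function(m) mean(df[[m]]), numeric(1))
    sg <- vapply(met, function(m)
      if (nrow(df) < 2) 0 else stats::sd(df[[m]]), numeric(1))
    dplyr::bind_rows(
      tibble::tibble(group = label, stat = "mean", !!!as.list(mu),
                     n_cases = nrow(df)),
      tibble::tibble(group = label, stat = "sd", !!!as.list(sg),
                     n_cases = nrow(df)))
  }
  out <- one(reports, "all")
  if (!is.null(group_labels)) {
    stopifnot(length(group_labels) == nrow(reports))
    for (g in unique(group_labels))
      out <- dplyr::bind_rows(out, one(reports[group_labels == g, , drop = FALSE], g))
  }
  out
}
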