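#' Segmentation evaluation metrics
#'
#' Four pixel-set metrics comparing a segmentation result (SR) with its
#' ground truth (GT), all expressed relative to pixel counts:
#' * true-positive rate `|GT intersect SR| / |GT|`,
#' * false-positive rate `|GT union SR - GT| / |GT| = |SR \ GT| / |GT|`
#'   (can exceed 1 when the spurious area outgrows the target; not clipped),
#' * Dice coefficient `2 |GT intersect SR| / (|GT| + |SR|)`,
#' * intersection over union `|GT intersect SR| / |GT union SR|`.
#'
#' With an empty GT, TP and FP are undefined and return `NA`; Dice and IoU
#' are 1 when both masks are empty and 0 when exactly one is.
#'
#' @param gt,sr binary (0/1) matrices of identical dimension.
#' @return A single numeric value (possibly `NA` for TP/FP with empty GT).
#' @name segmentation_metrics
NULL

.check_mask_pair <- function(gt, sr) {
  if (!identical(dim(gt), dim(sr))) {
    stop(sprintf("masks differ in shape: %s vs %s",
                 paste(dim(gt), collapse = "x"), paste(dim(sr), collapse = "x")),
         call. = FALSE)
  }
  if (!all(gt %in% c(0, 1)) || !all(sr %in% c(0, 1))) {
    stop("masks must be binary (0/1)", call. = FALSE)
  }
}

#' @rdname segmentation_metrics
#' @export
true_positive_rate <- function(gt, sr) {
  .check_mask_pair(gt, sr)
  n_gt <- sum(gt)
  if (n_gt == 0) return(NA_real_)
  sum(gt * sr) / n_gt
}

#' @rdname segmentation_metrics
#' @export
false_positive_rate <- function(gt, sr) {
  .check_mask_pair(gt, sr)
  n_gt <- sum(gt)
  if (n_gt == 0) return(NA_real_)
  sum(sr * (1 - gt)) / n_gt
}

#' @rdname segmentation_metrics
#' @export
dice <- function(gt, sr) {
  .check_mask_pair(gt, sr)
  denom <- sum(gt) + sum(sr)
  if (denom == 0) return(1)
  2 * sum(gt * sr) / denom
}

#' @rdname segmentation_metrics
#' @export
iou <- function(gt, sr) {
  .check_mask_pair(gt, sr)
  uni <- sum((gt + sr) > 0)
  if (uni == 0) return(1)
  sum(gt * sr) / uni
}

#' Per-image, per-output metric records
#'
#' Computes all four metrics for each channel combination of one image.
#'
#' @param gt_masks ground-truth [mask_set].
#' @param sr_masks predicted [mask_set] (e.g. `binary_masks` of a
#'   [segmentation_result]).
#' @param image_id identifier carried into the record.
#' @return A data frame with columns `image_id, combo, tp, fp, dc, iou`,
#'   one row per combination in canonical order.
#' @export
metric_records <- function(gt_masks, sr_masks, image_id = NA) {
  do.call(rbind, lapply(COMBOS, function(cmb) {
    gt <- gt_masks[[cmb]]; sr <- sr_masks[[cmb]]
    data.frame(image_id = image_id, combo = cmb,
               tp = true_positive_rate(gt, sr), fp = false_positive_rate(gt, sr),
               dc = dice(gt, sr), iou = iou(gt, sr))
  }))
}

#' Aggregate metric records into a cross-validation summary table
#'
#' Within each fold the records (all validation images x all outputs) are
#' averaged unweighted, skipping undefined (`NA`) TP/FP entries from
#' empty-GT cases.  The table then reports, per metric, the mean and the
#' sample (n-1) standard deviation across fold means; with a single fold
#' the standard deviation is 0.
#'
#' @param fold_records list with one metric-record data frame per fold (a
#'   single data frame is treated as one fold).
#' @return An object of class `metrics_table`: a data frame with columns
#'   `metric, mean, sd` for `dc, fp, iou, tp`, with the per-fold means in
#'   attribute `"fold_means"`.
#' @export
aggregate_metrics <- function(fold_records) {
  if (is.data.frame(fold_records)) fold_records <- list(fold_records)
  if (length(fold_records) == 0 ||
      any(!vapply(fold_records, function(f) is.data.frame(f) && nrow(f) > 0, logical(1)))) {
    stop("aggregate_metrics: need at least one fold with at least one record",
         call. = FALSE)
  }
  metrics <- c("dc", "fp", "iou", "tp")
  fold_means <- t(vapply(fold_records, function(f) {
    vapply(metrics, function(m) mean(f[[m]], na.rm = TRUE), numeric(1))
  }, numeric(length(metrics))))
  tab <- data.frame(
    metric = metrics,
    mean = colMeans(fold_means),
    sd = if (nrow(fold_means) > 1) apply(fold_means, 2, sd) else rep(0, length(metrics))
  )
  rownames(tab) <- NULL
  structure(tab, fold_means = fold_means, class = c("metrics_table", "data.frame"))
}

#' @export
print.metrics_table <- function(x, ...) {
  k <- nrow(attr(x, "fold_means"))
  cat(sprintf("Cross-validation summary (%d fold%s), mean +/- sd over fold means:\n",
              k, if (k == 1) "" else "s"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s %.4f +/- %.4f\n", toupper(x$metric[i]), x$mean[i], x$sd[i]))
  }
  invisible(x)
}
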