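#' Binarize a label volume into an evaluation region
#'
#' The three nested BraTS evaluation regions: enhancing tumor
#' ET = \{4\}, tumor core TC = \{1, 4\}, whole tumor WT = \{1, 2, 4\}.
#'
#' @param labels integer array with values in \{0, 1, 2, 4\}.
#' @param region \code{"ET"}, \code{"WT"} or \code{"TC"}.
#' @return logical array of the same shape.
#' @export
region_binarize <- function(labels, region) {
  validate_labels(labels)
  members <- switch(toupper(region),
                    ET = 4L, TC = c(1L, 4L), WT = c(1L, 2L, 4L),
                    stop_mtv("unknown region '%s' (expected ET, WT or TC)", region))
  out <- array(as.integer(labels) %in% members, dim = dim(labels))
  out
}

#' Voxel confusion counts between two binary masks
#'
#' @param gt,pred logical arrays of identical shape.
#' @return named list with TP, FP, FN, TN (counts summing to the voxel total).
#' @export
confusion_counts <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred)))
    stop_mtv("shape mismatch: gt %s vs pred %s",
             paste(dim(gt), collapse = "x"), paste(dim(pred), collapse = "x"))
  gt <- as.logical(gt); pred <- as.logical(pred)
  tp <- sum(gt & pred)
  fp <- sum(!gt & pred)
  fn <- sum(gt & !pred)
  list(TP = tp, FP = fp, FN = fn, TN = length(gt) - tp - fp - fn)
}

#' Dice score with the BraTS empty-region conventions
#'
#' \eqn{Dice = 2TP / (FN + FP + 2TP)}. When both ground truth and
#' prediction are empty the score is 1 by convention; when the ground truth
#' is empty but the prediction is not, the score is 0.
#'
#' @param counts confusion counts from [confusion_counts()].
#' @param gt_empty,pred_empty emptiness flags (derived from \code{counts}
#'   when omitted).
#' @return Dice in [0, 1].
#' @export
dice_score <- function(counts, gt_empty = (counts$TP + counts$FN) == 0,
                       pred_empty = (counts$TP + counts$FP) == 0) {
  if (gt_empty && pred_empty) return(1)
  if (gt_empty) return(0)
  denom <- counts$FN + counts$FP + 2 * counts$TP
  if (denom == 0) return(0)
  2 * counts$TP / denom
}

#' Sensitivity and specificity
#'
#' Sensitivity \eqn{TP/(TP+FN)} (fraction of true region voxels recovered)
#' and specificity \eqn{TN/(TN+FP)} (fraction of non-region voxels kept
#' clean). An undefined ratio (zero denominator) is reported as \code{NA},
#' not coerced to 0.
#'
#' @param counts confusion counts from [confusion_counts()].
#' @return named numeric vector \code{c(sensitivity, specificity)}.
#' @export
sensitivity_specificity <- function(counts) {
  sens <- if (counts$TP + counts$FN == 0) NA_real_ else
    counts$TP / (counts$TP + counts$FN)
  spec <- if (counts$TN + counts$FP == 0) NA_real_ else
    counts$TN / (counts$TN + counts$FP)
  c(sensitivity = sens, specificity = spec)
}

#' 95th-percentile Hausdorff distance
#'
#' Robust surface-distance metric: for each direction, the distances from
#' every voxel of one mask to the nearest voxel of the other are collected
#' and their 95th percentile taken (linear interpolation); the two directed
#' values are symmetrized by the maximum. Identical non-empty masks give 0.
#' Undefined (returns \code{NA}) when either mask is empty; such cases are
#' excluded from summary means.
#'
#' @param gt,pred logical arrays of identical shape.
#' @param spacing voxel spacing in mm (default unit, i.e. voxel units).
#' @param percentile percentile of the directed distances (default 95).
#' @return distance (same units as \code{spacing}), or \code{NA}.
#' @export
hausdorff95 <- function(gt, pred, spacing = c(1, 1, 1), percentile = 95) {
  if (!identical(dim(gt), dim(pred)))
    stop_mtv("shape mismatch: gt %s vs pred %s",
             paste(dim(gt), collapse = "x"), paste(dim(pred), collapse = "x"))
  shp <- dim(gt)
  gt <- as.logical(gt); dim(gt) <- shp
  pred <- as.logical(pred); dim(pred) <- shp
  if (!any(gt) || !any(pred)) return(NA_real_)
  d_to_gt <- distance_to_mask(gt, spacing)
  d_to_pred <- distance_to_mask(pred, spacing)
  q <- percentile / 100
  max(quantile(d_to_gt[pred], q, names = FALSE, type = 7),
      quantile(d_to_pred[gt], q, names = FALSE, type = 7))
}

#' Enhancing-tumor post-processing rule
#'
#' Small predicted enhancing-tumor components are usually false positives
#' that are punished harshly by the empty-ET Dice convention. If the total
#' number of predicted ET voxels (label 4) is strictly below
#' \code{threshold}, every ET voxel is relabeled as necrosis (label 1), i.e.
#' folded into the tumor core. The WT and TC binary regions are invariant
#' under this operation, and the ET count never increases.
#'
#' @param pred integer label array with values in \{0, 1, 2, 4\}.
#' @param threshold voxel-count threshold (default 500; strict inequality).
#' @return relabeled array.
#' @export
postprocess_enhancing_tumor <- function(pred, threshold = 500) {
  if (threshold < 0) stop_mtv("threshold must be >= 0")
  validate_labels(pred)
  n_et <- sum(pred == 4L)
  if (n_et > 0 && n_et < threshold) pred[pred == 4L] <- 1L
  pred
}

#' Per-case evaluation over the ET/WT/TC regions
#'
#' @param gt,pred integer label arrays with values in \{0, 1, 2, 4\}.
#' @param spacing voxel spacing for Hausdorff95.
#' @param case identifier recorded in the output.
#' @return data.frame with one row per region: Dice, sensitivity,
#'   specificity, Hausdorff95 and the confusion counts.
#' @export
case_metrics <- function(gt, pred, spacing = c(1, 1, 1), case = "case") {
  regions <- c("ET", "WT", "TC")
  rows <- lapply(regions, function(r) {
    g <- region_binarize(gt, r)
    p <- region_binarize(pred, r)
    cc <- confusion_counts(g, p)
    ss <- sensitivity_specificity(cc)
    data.frame(case = case, region = r,
               dice = dice_score(cc),
               sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]],
               hausdorff95 = hausdorff95(g, p, spacing),
               TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a per-case metrics table
#'
#' Mean and median of each metric per region; undefined (NA) Hausdorff95 or
#' sensitivity values are excluded, and the number of excluded cases is
#' reported.
#'
#' @param metrics data.frame from [case_metrics()] rows.
#' @return data.frame with one row per region and statistic.
#' @export
summarize_metrics <- function(metrics) {
  out <- lapply(split(metrics, metrics$region), function(df) {
    data.frame(region = df$region[1],
               dice_mean = mean(df$dice, na.rm = TRUE),
               dice_median = stats::median(df$dice, na.rm = TRUE),
               sensitivity_mean = mean(df$sensitivity, na.rm = TRUE),
               specificity_mean = mean(df$specificity, na.rm = TRUE),
               hausdorff95_mean = mean(df$hausdorff95, na.rm = TRUE),
               hausdorff95_excluded = sum(is.na(df$hausdorff95)),
               n_cases = nrow(df), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
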