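#' Multilabel classification metrics
#'
#' Per-class binary confusion counts at the decision threshold, the standard
#' accuracy/precision/recall/F1 formulas, per-class one-vs-rest AUC over the
#' continuous probabilities, and their unweighted (macro) averages. A class
#' with no positive labels has undefined recall (and AUC); such values are
#' reported as `NA` and excluded from the macro averages with a warning.
#'
#' @param probs `N x K` matrix of class probabilities.
#' @param labels `N x K` 0/1 matrix of ground truth.
#' @param threshold decision cutoff in (0,1).
#' @return a `class_metrics` object: list with `per_class` (data frame:
#'   tp/fp/fn/tn, accuracy, precision, recall, f1, auc), `macro` (named
#'   vector), `threshold`, `n_samples`.
#' @export
classification_metrics <- function(probs, labels, threshold = 0.5) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  if (!all(dim(probs) == dim(labels)))
    stopf("probs (%s) and labels (%s) shapes differ",
          paste(dim(probs), collapse = "x"),
          paste(dim(labels), collapse = "x"))
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0,1)")
  k <- ncol(probs)
  pred <- (probs >= threshold) * 1L
  rows <- lapply(seq_len(k), function(j) {
    y <- labels[, j]; p <- pred[, j]
    tp <- sum(p == 1 & y == 1); fp <- sum(p == 1 & y == 0)
    fn <- sum(p == 0 & y == 1); tn <- sum(p == 0 & y == 0)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    # direct form 2TP/(2TP+FP+FN): 0 for a complete miss, undefined only
    # when the class is absent from both truth and prediction
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    data.frame(class = j, tp = tp, fp = fp, fn = fn, tn = tn,
               accuracy = (tp + tn) / length(y), precision = prec,
               recall = rec, f1 = f1,
               auc = binary_auc(probs[, j], y))
  })
  per_class <- do.call(rbind, rows)
  if (anyNA(per_class[, c("precision", "recall", "f1", "auc")]))
    warnf("undefined per-class metrics (degenerate labels or predictions) %s",
          "excluded from macro averages")
  macro <- c(accuracy = mean(per_class$accuracy),
             precision = mean(per_class$precision, na.rm = TRUE),
             recall = mean(per_class$recall, na.rm = TRUE),
             f1 = mean(per_class$f1, na.rm = TRUE),
             auc = mean(per_class$auc, na.rm = TRUE))
  structure(list(per_class = per_class, macro = macro, threshold = threshold,
                 n_samples = nrow(probs)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("class_metrics: %d samples, threshold %.2f\n", x$n_samples,
              x$threshold))
  print(round(x$per_class[, -1], 3))
  cat("macro: ", paste(sprintf("%s=%.3f", names(x$macro), x$macro),
                       collapse = " "), "\n")
  invisible(x)
}

# One-vs-rest AUC for a single class; NA when only one label value present.
binary_auc <- function(p, y) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<",
                                 levels = c(0, 1))))
}

#' Macro-averaged one-vs-rest AUC
#'
#' @param probs `N x K` probability matrix.
#' @param labels `N x K` 0/1 matrix.
#' @return mean of the defined per-class AUCs (classes whose test labels are
#'   single-valued are flagged with a warning and skipped).
#' @export
macro_auc <- function(probs, labels) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  aucs <- vapply(seq_len(ncol(probs)),
                 function(j) binary_auc(probs[, j], labels[, j]), numeric(1))
  if (anyNA(aucs))
    warnf("AUC undefined for class(es) %s (single-valued labels)",
          paste(which(is.na(aucs)), collapse = ", "))
  mean(aucs, na.rm = TRUE)
}

#' Binarize a normalized activation map
#'
#' @param display matrix with values in \[0,1\] (e.g. `display$norm` of a
#'   post-processed Grad-CAM map).
#' @param threshold cutoff in (0,1); a pixel is set iff its value is
#'   `>= threshold`.
#' @return logical matrix.
#' @export
binarize_cam <- function(display, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must be in (0,1), got %s", format(threshold))
  display >= threshold
}

#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`. When both masks are empty the ratio is
#' taken as 1 (correctly predicted absence); aggregate functions exclude such
#' cases by default.
#'
#' @param mask_a,mask_b logical matrices of equal shape.
#' @return scalar IoU in \[0,1\].
#' @export
compute_iou <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stopf("mask shapes differ: %s vs %s",
          paste(dim(mask_a), collapse = "x"),
          paste(dim(mask_b), collapse = "x"))
  u <- sum(mask_a | mask_b)
  if (u == 0) return(1)
  sum(mask_a & mask_b) / u
}

#' Mean IoU across classes
#'
#' Computes the per-class IoU between predicted (e.g. binarized Grad-CAM) and
#' reference (expert ROI) masks and their unweighted mean. Classes whose
#' reference mask is empty (no ROI in the evaluation set) are excluded from
#' the mean with a warning.
#'
#' @param cam_masks named list of logical matrices, one per class.
#' @param roi_masks named list of logical matrices over the same classes.
#' @param threshold the binarization cutoff the CAM masks were produced with
#'   (recorded in the report; default NA).
#' @return an `iou_report`: list with `per_class_iou`, `n_classes` (number of
#'   classes entering the mean), `miou`, `threshold`.
#' @export
compute_miou <- function(cam_masks, roi_masks, threshold = NA_real_) {
  if (length(cam_masks) == 0) stopf("empty class set")
  if (!identical(names(cam_masks), names(roi_masks)) ||
      length(cam_masks) != length(roi_masks))
    stopf("cam_masks and roi_masks must cover the same class set")
  ious <- mapply(compute_iou, cam_masks, roi_masks)
  names(ious) <- names(cam_masks) %||% paste0("class_", seq_along(ious))
  keep <- vapply(roi_masks, function(m) sum(m) > 0, logical(1))
  if (!all(keep))
    warnf("class(es) %s have no reference ROI and are excluded from mIoU",
          paste(names(ious)[!keep], collapse = ", "))
  structure(list(per_class_iou = ious, n_classes = sum(keep),
                 miou = mean(ious[keep]), threshold = threshold),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat(sprintf("iou_report: mIoU %.3f over %d class(es)%s\n", x$miou,
              x$n_classes,
              if (is.na(x$threshold)) "" else
                sprintf(" (CAM threshold %.2f)", x$threshold)))
  print(round(x$per_class_iou, 3))
  invisible(x)
}

#' Score Grad-CAM explanations against expert ROIs over a phantom dataset
#'
#' For every sample and every evaluated class (ground-truth positives by
#' default, or thresholded predictions), the class CAM is post-processed to
#' image resolution, binarized, and compared with the union of the sample's
#' ellipse ROI masks for that class. Reports the per-class mean IoU, the
#' grand means with dispersion both across classes and across images, and
#' the localization hit rate (fraction of maps whose argmax falls inside the
#' ROI).
#'
#' @param model a trained `gf_model`.
#' @param dataset the `phantom_dataset` the inputs came from.
#' @param x input batch matching `dataset` (e.g. from [build_inputs()]).
#' @param target_layer hooked layer for [capture_activations()].
#' @param cam_threshold binarization cutoff for the normalized CAM.
#' @param class_mode `"truth"` evaluates ground-truth positive classes,
#'   `"pred"` the model's thresholded predicted positives.
#' @param pred_threshold decision cutoff for `class_mode = "pred"`.
#' @return list with `per_class_iou`, `miou`, `sd_class`, `mean_image`,
#'   `sd_image`, `hit_rate`, `n_maps`, `cam_threshold`.
#' @export
evaluate_explanations <- function(model, dataset, x, target_layer = "conv2",
                                  cam_threshold = 0.5,
                                  class_mode = c("truth", "pred"),
                                  pred_threshold = 0.5) {
  class_mode <- match.arg(class_mode)
  x <- as_batch(x)
  cfg <- attr(dataset, "config")
  size <- cfg$image_size
  probs <- if (class_mode == "pred") model_predict(model, x) else NULL
  ious <- vector("list", cfg$n_classes)
  img_ious <- numeric(0)
  hits <- 0; n_maps <- 0
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    cls <- if (class_mode == "truth") which(s$labels == 1) else
      which(probs[i, ] >= pred_threshold)
    cls <- cls[vapply(cls, function(k)
      any(vapply(s$rois, function(r) r$class == k, logical(1))), logical(1))]
    if (length(cls) == 0) next
    per_image <- numeric(0)
    for (k in cls) {
      roi_mask <- Reduce(`|`, lapply(Filter(function(r) r$class == k, s$rois),
                                     ellipse_to_mask, width = size,
                                     height = size))
      cam <- postprocess_cam(gradcam(capture_activations(
        model, x[, , , i, drop = FALSE], k, target_layer)), size, size)
      iou <- compute_iou(binarize_cam(cam$display$norm, cam_threshold),
                         roi_mask)
      ious[[k]] <- c(ious[[k]], iou)
      per_image <- c(per_image, iou)
      am <- which(cam$display$norm == max(cam$display$norm),
                  arr.ind = TRUE)[1, ]
      hits <- hits + roi_mask[am[1], am[2]]
      n_maps <- n_maps + 1
    }
    img_ious <- c(img_ious, mean(per_image))
  }
  per_class <- vapply(ious, function(v) if (length(v)) mean(v) else NA_real_,
                      numeric(1))
  names(per_class) <- paste0("class_", seq_len(cfg$n_classes))
  list(per_class_iou = per_class,
       miou = mean(per_class, na.rm = TRUE),
       sd_class = stats::sd(per_class[!is.na(per_class)]),
       mean_image = mean(img_ious), sd_image = stats::sd(img_ious),
       hit_rate = if (n_maps > 0) hits / n_maps else NA_real_,
       n_maps = n_maps, cam_threshold = cam_threshold)
}
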